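# Synthetic SBP-domain consensus (76 aa).
# This is NOT the Pfam PF03110 seed: it is a constructed stand-in that
# reproduces the hallmark architecture of the plant SBP DNA-binding domain
# (two zinc-finger-like Cys/His clusters followed by a basic NLS-like
# C-terminal stretch) for use in simulations and domain-scan tests.
RLCQVEGCGLDLSSAKDYHRRHKVCEMHSKASKALVGNVMQRFCQQCSRFHLLSEFDEGKRSCRRRLAGHNERRRK
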