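# ceRNA-miRNA-mRNA triad construction: shared-MRE pairs, correlation
# filtering, direction-gated assembly per stage contrast, network export and
# evaluation against planted truth.

#' Candidate ceRNA-mRNA pairs sharing miRNA response elements
#'
#' One pair per (ceRNA, mRNA) combination whose MRE sets intersect; the
#' shared miRNAs are recorded. ceRNAs are the lncRNA and circRNA entries of
#' the MRE table, targets the mRNA entries.
#'
#' @param mre_table MRE table from [predict_targetome()].
#' @return `data.frame` with columns `cerna_id`, `cerna_biotype`,
#'   `mrna_id`, `shared_mirnas` (list column), `n_shared`.
#' @export
shared_mre_pairs <- function(mre_table) {
  stopifnot(all(c("mirna_id", "target_id", "biotype") %in% names(mre_table)))
  ce <- unique(mre_table[mre_table$biotype %in% c("lncRNA", "circRNA"),
                         c("mirna_id", "target_id", "biotype")])
  mr <- unique(mre_table[mre_table$biotype == "mRNA",
                         c("mirna_id", "target_id")])
  if (nrow(ce) == 0L || nrow(mr) == 0L) {
    return(data.frame(cerna_id = character(0), cerna_biotype = character(0),
                      mrna_id = character(0),
                      shared_mirnas = I(list()), n_shared = integer(0)))
  }
  joined <- merge(ce, mr, by = "mirna_id",
                  suffixes = c("_cerna", "_mrna"))
  key <- paste(joined$target_id_cerna, joined$target_id_mrna, sep = "\r")
  split_mir <- split(joined$mirna_id, key)
  first <- joined[!duplicated(key), , drop = FALSE]
  ord_key <- paste(first$target_id_cerna, first$target_id_mrna, sep = "\r")
  out <- data.frame(
    cerna_id = first$target_id_cerna,
    cerna_biotype = first$biotype,
    mrna_id = first$target_id_mrna,
    stringsAsFactors = FALSE
  )
  out$shared_mirnas <- I(lapply(split_mir[ord_key], function(x) sort(unique(x))))
  out$n_shared <- vapply(out$shared_mirnas, length, integer(1))
  out <- out[order(out$cerna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidate pairs by expression correlation
#'
#' Annotates each pair with the Pearson correlation of the two members'
#' per-stage mean expression profiles and keeps pairs with a defined
#' correlation at or above `r_min`. Only positive thresholds are accepted:
#' the ceRNA hypothesis requires co-varying profiles. Pairs with a member
#' missing from the expression matrix are dropped with a message.
#'
#' @param pairs Output of [shared_mre_pairs()].
#' @param expr Stage-mean expression matrix (features x stages) covering
#'   both ceRNAs and mRNAs (on their respective normalization scales;
#'   Pearson correlation is scale-invariant per feature).
#' @param r_min Minimum correlation (default 0.8; must be > 0).
#' @return The filtered pairs with an added `r` column.
#' @export
correlation_filter <- function(pairs, expr, r_min = 0.8) {
  if (!(r_min > 0)) stop_config("r_min", "must be > 0")
  if (nrow(pairs) == 0L) {
    pairs$r <- numeric(0)
    return(pairs)
  }
  have <- rownames(expr)
  missing <- !(pairs$cerna_id %in% have) | !(pairs$mrna_id %in% have)
  if (any(missing)) {
    message(sprintf("dropping %d pair(s) with missing expression", sum(missing)))
    pairs <- pairs[!missing, , drop = FALSE]
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- expr[pairs$cerna_id[i], ]
    y <- expr[pairs$mrna_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  pairs$r <- r
  out <- pairs[!is.na(r) & r >= r_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble ceRNA-miRNA-mRNA triads per stage contrast
#'
#' A triad (ceRNA, miRNA, mRNA) is emitted for a contrast when (i) the pair
#' shares that miRNA's response element and passed the correlation filter,
#' (ii) ceRNA and mRNA are differentially expressed in the same direction
#' with |log2fc| >= `de_threshold`, and (iii) the shared miRNA is
#' differentially expressed in the opposite direction (the sponge
#' signature; relax with `require_mirna_de = FALSE`). Multiple MREs for the
#' same pair and miRNA collapse to one triad.
#'
#' @param pairs Correlation-filtered pairs (from [correlation_filter()]).
#' @param contrasts Combined contrast table over all biotypes (columns
#'   `feature`, `contrast`, `log2fc`, `direction`, `fold_bin`), e.g. rbind
#'   of [contrast_stages()] outputs for FPKM/TPM/RPM matrices.
#' @param de_threshold Minimum |log2fc| (default 1, i.e. two-fold).
#' @param require_mirna_de Require the opposite-direction miRNA gate
#'   (default `TRUE`).
#' @return `data.frame` with one row per (ceRNA, miRNA, mRNA, contrast):
#'   ids, contrast, the three log2fc values, fold bins with direction, and
#'   `r`.
#' @export
assemble_triads <- function(pairs, contrasts, de_threshold = 1,
                            require_mirna_de = TRUE) {
  stopifnot(all(c("feature", "contrast", "log2fc", "direction", "fold_bin")
                %in% names(contrasts)))
  out <- list()
  for (ctr in unique(contrasts$contrast)) {
    cc <- contrasts[contrasts$contrast == ctr, , drop = FALSE]
    lfc <- setNames(cc$log2fc, cc$feature)
    dirn <- setNames(cc$direction, cc$feature)
    bin <- setNames(paste(ifelse(cc$direction == "up", "Up", "Down"),
                          cc$fold_bin), cc$feature)
    for (i in seq_len(nrow(pairs))) {
      ce <- pairs$cerna_id[i]
      mr <- pairs$mrna_id[i]
      if (is.na(lfc[ce]) || is.na(lfc[mr])) next
      de_ok <- abs(lfc[ce]) >= de_threshold && abs(lfc[mr]) >= de_threshold &&
        dirn[ce] == dirn[mr] && dirn[ce] %in% c("up", "down")
      if (!de_ok) next
      for (mir in pairs$shared_mirnas[[i]]) {
        if (require_mirna_de) {
          if (is.na(lfc[mir])) next
          opposite <- (dirn[ce] == "up" && dirn[mir] == "down") ||
            (dirn[ce] == "down" && dirn[mir] == "up")
          if (!(abs(lfc[mir]) >= de_threshold && opposite)) next
        }
        out[[length(out) + 1L]] <- data.frame(
          cerna_id = ce, mirna_id = mir, mrna_id = mr, contrast = ctr,
          cerna_log2fc = unname(lfc[ce]),
          mirna_log2fc = unname(if (mir %in% names(lfc)) lfc[mir] else NA_real_),
          mrna_log2fc = unname(lfc[mr]),
          cerna_bin = unname(bin[ce]),
          mirna_bin = unname(if (mir %in% names(bin)) bin[mir] else NA_character_),
          mrna_bin = unname(bin[mr]),
          r = pairs$r[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cerna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), contrast = character(0),
                      cerna_log2fc = numeric(0), mirna_log2fc = numeric(0),
                      mrna_log2fc = numeric(0), cerna_bin = character(0),
                      mirna_bin = character(0), mrna_bin = character(0),
                      r = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a triad network in Cytoscape-compatible formats
#'
#' Writes a SIF edge list (`cerna_mirna` and `mirna_mrna` edges), a node
#' attribute TSV (biotype and the Up/Down fold-bin label per node) and a
#' GraphML file with the same content.
#'
#' @param triads Triad table from [assemble_triads()] (typically one
#'   contrast).
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"network"`).
#' @param biotypes Optional named vector feature id -> biotype used for the
#'   node table; inferred roles are used when absent.
#' @return Character vector of the written paths (sif, nodes, graphml).
#' @export
export_network <- function(triads, dir, prefix = "network", biotypes = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
  }
  sif_path <- file.path(dir, paste0(prefix, ".sif"))
  nodes_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  graphml_path <- file.path(dir, paste0(prefix, ".graphml"))

  edges <- unique(rbind(
    data.frame(source = triads$cerna_id, interaction = "cerna_mirna",
               target = triads$mirna_id, stringsAsFactors = FALSE),
    data.frame(source = triads$mirna_id, interaction = "mirna_mrna",
               target = triads$mrna_id, stringsAsFactors = FALSE)
  ))
  writeLines(sprintf("%s\t%s\t%s", edges$source, edges$interaction,
                     edges$target), sif_path)

  nodes <- unique(rbind(
    data.frame(node = triads$cerna_id, role = "ceRNA",
               bin = triads$cerna_bin, stringsAsFactors = FALSE),
    data.frame(node = triads$mirna_id, role = "miRNA",
               bin = triads$mirna_bin, stringsAsFactors = FALSE),
    data.frame(node = triads$mrna_id, role = "mRNA",
               bin = triads$mrna_bin, stringsAsFactors = FALSE)
  ))
  nodes <- nodes[!duplicated(nodes$node), , drop = FALSE]
  if (!is.null(biotypes)) {
    nodes$biotype <- unname(biotypes[nodes$node])
  } else {
    nodes$biotype <- nodes$role
  }
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "interaction")], directed = TRUE,
      vertices = nodes)
  } else {
    g <- igraph::make_empty_graph()
  }
  igraph::write_graph(g, graphml_path, format = "graphml")
  c(sif = sif_path, nodes = nodes_path, graphml = graphml_path)
}

#' Evaluate triad recovery against planted truth
#'
#' Set comparison on (ceRNA, miRNA, mRNA) keys. When `contrast` is given,
#' only triads of that contrast are compared; otherwise predicted keys are
#' pooled over contrasts. An empty prediction with non-empty truth reports
#' recall 0 and precision 0 with `precision_defined = FALSE`.
#'
#' @param triads Triad table from [assemble_triads()].
#' @param planted_triads Truth table (`cerna_id`, `mirna_id`, `mrna_id`).
#' @param contrast Optional contrast label to restrict the comparison.
#' @return List with `precision`, `recall`, `precision_defined`,
#'   `n_predicted`, `n_truth`, `true_positives`, `false_positives`,
#'   `false_negatives` (key vectors).
#' @export
evaluate_recovery <- function(triads, planted_triads, contrast = NULL) {
  if (!is.null(contrast)) {
    triads <- triads[triads$contrast == contrast, , drop = FALSE]
  }
  pred <- unique(paste(triads$cerna_id, triads$mirna_id, triads$mrna_id,
                       sep = "|"))
  truth <- unique(paste(planted_triads$cerna_id, planted_triads$mirna_id,
                        planted_triads$mrna_id, sep = "|"))
  tp <- intersect(pred, truth)
  list(
    precision = if (length(pred) > 0L) length(tp) / length(pred) else 0,
    recall = if (length(truth) > 0L) length(tp) / length(truth) else NA_real_,
    precision_defined = length(pred) > 0L,
    n_predicted = length(pred),
    n_truth = length(truth),
    true_positives = tp,
    false_positives = setdiff(pred, truth),
    false_negatives = setdiff(truth, pred)
  )
}
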