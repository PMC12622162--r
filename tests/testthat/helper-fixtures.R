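# Small programmatic fixtures shared across test files.

make_variants <- function(n = 3, chrom = "1") {
  bases <- c("A", "C", "G", "T")
  tibble::tibble(
    chrom = chrom,
    pos = seq_len(n) * 100L,
    ref = rep_len(bases, n),
    alt = rep_len(bases[c(2, 3, 4, 1)], n),
    gene = rep_len(c("GENE1", "GENE2"), n)
  )
}

make_registry_list <- function() {
  list(
    A = list(training_variants = list("1:100:A:C"), components = list(),
             clinical_trained = TRUE),
    B = list(training_variants = list("1:200:C:G"), components = list()),
    M = list(training_variants = list(), components = list("A", "B"))
  )
}

# random acyclic registry: component edges only from later to earlier tools
random_acyclic_registry <- function(n_tools, keys, edge_prob = 0.4) {
  ids <- sprintf("T%02d", seq_len(n_tools))
  tools <- stats::setNames(lapply(seq_len(n_tools), function(i) {
    comp <- if (i > 1) ids[seq_len(i - 1)][runif(i - 1) < edge_prob] else
      character(0)
    list(
      training_variants = as.list(sample(keys, sample(0:min(3, length(keys)), 1))),
      components = as.list(comp)
    )
  }), ids)
  as_tool_registry(tools)
}

# reachability oracle: recursive depth-first search over components
dfs_effective <- function(registry, tool) {
  comp <- stats::setNames(registry$components, registry$tool_id)
  tv <- stats::setNames(registry$training_variants, registry$tool_id)
  seen <- character(0)
  visit <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    for (c in comp[[t]]) visit(c)
  }
  visit(tool)
  sort(unique(unlist(tv[seen], use.names = FALSE)))
}

# brute-force AUC over all positive-negative pairs
pairs_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
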