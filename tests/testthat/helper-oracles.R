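# Independent oracles used across the suite. These deliberately take the
# brute-force route (eigendecomposition of the explicit covariance, per-base
# interval scans, exhaustive set logic, closed-form recursions) so that they
# share no code with the implementation they check.

# PCA oracle: eigendecomposition of the sample covariance of isolates x
# mutations data. Returns variance fractions and unit-norm eigenvectors.
oracle_cov_pca <- function(mat) {
  x <- t(mat)                               # isolates x mutations
  s <- stats::cov(x)
  e <- eigen(s, symmetric = TRUE)
  total <- sum(diag(s))
  keep <- e$values > max(e$values[1], 0) * 1e-10 & e$values > 0
  list(variance_fraction = e$values[keep] / total,
       loadings = e$vectors[, keep, drop = FALSE])
}

# Interval-overlap oracle: per-base scan of every mutation footprint against
# every gene, ties broken by smaller start then lexicographic gene id.
oracle_assign <- function(muts, genes) {
  out <- character(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    len <- if (muts$type[i] == "DEL") as.integer(muts$detail[i]) else 1L
    span <- muts$position[i]:(muts$position[i] + len - 1L)
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (genes$seq_id[j] != muts$seq_id[i]) next
      if (any(span %in% genes$start[j]:genes$end[j])) {
        hits <- c(hits, genes$gene_id[j])
      }
    }
    if (length(hits) == 0) {
      out[i] <- "intergenic"
    } else {
      ord <- order(genes$start[match(hits, genes$gene_id)], hits)
      out[i] <- hits[ord][1]
    }
  }
  out
}

# Gene-exclusion oracle: exhaustive set logic. A gene is tainted iff any of
# its mutations has delta < 0; retained = intergenic or in untainted gene.
oracle_gene_filter <- function(mutation_id, delta, gene_id) {
  tainted <- unique(gene_id[delta < 0 & gene_id != "intergenic"])
  mutation_id[gene_id == "intergenic" | !(gene_id %in% tainted)]
}

# Closed-form haploid selection recursion per transfer of g generations.
oracle_selection_traj <- function(x0, s, g, n_transfers) {
  x <- numeric(n_transfers)
  cur <- x0
  for (t in seq_len(n_transfers)) {
    cur <- cur * (1 + s)^g / (cur * (1 + s)^g + (1 - cur))
    x[t] <- cur
  }
  x
}

# Small record-table builder for I/O and matrix tests.
make_records <- function(n, seed = 1, isolates = c("iso1", "iso2")) {
  set.seed(seed)
  pos <- sample.int(1e6, n)
  type <- sample(c("SNP", "INS", "DEL"), n, replace = TRUE)
  detail <- vapply(type, function(tp) switch(tp,
    SNP = paste0(sample(c("A", "C", "G", "T"), 1), ">",
                 sample(c("A", "C", "G", "T"), 1)),
    INS = paste(sample(c("A", "C", "G", "T"), sample.int(6, 1), replace = TRUE),
                collapse = ""),
    DEL = as.character(sample.int(30, 1))), character(1))
  tibble::tibble(
    mutation_id = mutation_key("chr1", pos, type, detail),
    type = type, seq_id = "chr1", position = pos, detail = detail,
    isolate_id = sample(isolates, n, replace = TRUE),
    frequency = round(stats::runif(n), 4)
  )
}

# Panel helper: three parental + three evolved isolate labels.
panel_33 <- function() {
  tibble::tibble(isolate_id = c("OMP_1", "OMP_2", "OMP_3",
                                "EMP_1", "EMP_2", "EMP_3"),
                 group = rep(c("parental", "evolved"), each = 3))
}

# Frequency-matrix builder from a dense matrix + groups, via the public API.
fm_from_matrix <- function(mat, groups) {
  iso <- tibble::tibble(isolate_id = colnames(mat), group = groups)
  recs <- tibble::as_tibble(as.data.frame.table(mat, stringsAsFactors = FALSE))
  names(recs) <- c("mutation_id", "isolate_id", "frequency")
  recs <- recs[recs$frequency != 0, ]
  recs$type <- "SNP"
  recs$seq_id <- "chr1"
  recs$position <- match(recs$mutation_id, rownames(mat))
  recs$detail <- "A>C"
  fm <- build_matrix(recs, iso)
  # restore full row set/order (rows that are all zero drop out of records)
  mat2 <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  mat2[rownames(fm$mat), colnames(fm$mat)] <- fm$mat
  fm$mat <- mat2
  fm
}
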