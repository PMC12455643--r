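GROUPS <- c("parental", "evolved")

#' Build a mutation-by-isolate frequency matrix
#'
#' Collects per-isolate read-support frequencies into the central object of
#' the prioritization: one row per unique mutation, one column per isolate,
#' with the isolate panel's parental/evolved group labels attached. Cells
#' with no observation are 0 — polymorphism-mode callers simply omit absent
#' variants, so absence is taken as frequency zero.
#'
#' @param records A data frame of mutation records (columns as in
#'   [read_frequency_table()]).
#' @param isolates A data frame with columns `isolate_id` and `group`
#'   (`"parental"` or `"evolved"`), one row per isolate in the panel.
#' @return A `freq_matrix` object: a list with `mat` (numeric matrix,
#'   mutations x isolates) and `isolates` (the panel tibble). Use
#'   [generics::tidy()] for a long tibble view.
#' @export
build_matrix <- function(records, isolates) {
  records <- validate_records(records)
  stopifnot(is.data.frame(isolates))
  if (!all(c("isolate_id", "group") %in% names(isolates))) {
    stop("`isolates` needs columns isolate_id and group", call. = FALSE)
  }
  isolates <- tibble::tibble(isolate_id = as.character(isolates$isolate_id),
                             group = as.character(isolates$group))
  if (anyDuplicated(isolates$isolate_id)) {
    stop("duplicate isolate_id in panel", call. = FALSE)
  }
  if (!all(isolates$group %in% GROUPS)) {
    stop("isolate group labels must be 'parental' or 'evolved'", call. = FALSE)
  }
  if (!all(GROUPS %in% isolates$group)) {
    stop("panel needs at least one parental and one evolved isolate", call. = FALSE)
  }
  unknown <- setdiff(records$isolate_id, isolates$isolate_id)
  if (length(unknown) > 0) {
    stop("records reference isolate(s) not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records[, c("mutation_id", "isolate_id")])) {
    dup <- records[duplicated(records[, c("mutation_id", "isolate_id")]), ]
    stop("duplicate observation for (mutation, isolate): ",
         paste(dup$mutation_id[1], dup$isolate_id[1], sep = ", "), call. = FALSE)
  }
  mut_ids <- unique(records$mutation_id)
  mat <- matrix(0, nrow = length(mut_ids), ncol = nrow(isolates),
                dimnames = list(mut_ids, isolates$isolate_id))
  if (nrow(records) > 0) {
    mat[cbind(match(records$mutation_id, mut_ids),
              match(records$isolate_id, isolates$isolate_id))] <- records$frequency
  }
  structure(list(mat = mat, isolates = isolates), class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat("<freq_matrix> ", nrow(x$mat), " mutations x ", ncol(x$mat),
      " isolates (", sum(x$isolates$group == "parental"), " parental, ",
      sum(x$isolates$group == "evolved"), " evolved)\n", sep = "")
  invisible(x)
}

#' @export
tidy.freq_matrix <- function(x, ...) {
  long <- tibble::as_tibble(as.data.frame.table(x$mat, stringsAsFactors = FALSE))
  names(long) <- c("mutation_id", "isolate_id", "frequency")
  dplyr::left_join(long, x$isolates, by = "isolate_id")
}

#' Principal component analysis of a frequency matrix
#'
#' Isolates are the observations and mutations the features. Features are
#' centered by their across-isolate mean but not rescaled (all features share
#' the read-support-fraction unit), and the components are obtained from the
#' singular value decomposition of the centered matrix. Loadings are
#' unit-norm; each component's sign is fixed so that its largest-magnitude
#' loading is positive. `variance_fraction` is each component's share of the
#' total feature variance.
#'
#' @param fm A `freq_matrix` from [build_matrix()].
#' @return An `ale_pca` object: `scores` (isolates x components), `loadings`
#'   (mutations x components), `variance_fraction`, and the isolate panel.
#' @export
run_pca <- function(fm) {
  stopifnot(inherits(fm, "freq_matrix"))
  x <- t(fm$mat)                       # isolates x mutations
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 isolates", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  total_ss <- sum(xc^2)
  if (total_ss <= 0 || !is.finite(total_ss)) {
    stop("degenerate input: no mutation varies across isolates", call. = FALSE)
  }
  sv <- svd(xc)
  r <- sum(sv$d > sv$d[1] * 1e-12)
  r <- min(r, n - 1)
  d <- sv$d[seq_len(r)]
  u <- sv$u[, seq_len(r), drop = FALSE]
  v <- sv$v[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, nrow = r)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(r)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(r)))
  structure(list(
    scores = scores,
    loadings = v,
    variance_fraction = d^2 / total_ss,
    isolates = fm$isolates
  ), class = "ale_pca")
}

#' @export
print.ale_pca <- function(x, ...) {
  cat("<ale_pca> ", nrow(x$loadings), " mutations, ", nrow(x$scores),
      " isolates, ", length(x$variance_fraction), " components\n", sep = "")
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn run_pca Long tibble of loadings (one row per mutation per
#'   component).
#' @param x An `ale_pca` object.
#' @param ... Unused.
#' @export
tidy.ale_pca <- function(x, ...) {
  long <- tibble::as_tibble(as.data.frame.table(x$loadings, stringsAsFactors = FALSE))
  names(long) <- c("mutation_id", "component", "loading")
  long
}

#' @describeIn run_pca One-row summary: number of components and the variance
#'   fractions of the first two.
#' @export
glance.ale_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble::tibble(
    n_components = length(vf),
    var_frac_pc1 = vf[1],
    var_frac_pc2 = if (length(vf) >= 2) vf[2] else NA_real_,
    total_var_frac = sum(vf)
  )
}

#' Select principal components that discriminate parental from evolved
#'
#' A component is selected when the separation of its scores between the two
#' groups — absolute difference of group means over the pooled within-group
#' standard deviation — reaches `tau`. When there is no within-group spread
#' at all but the means differ, separation is taken as infinite and the
#' component is selected. This formalizes the by-eye choice of components
#' that split parental and evolved isolates in a score plot.
#'
#' @param pca An `ale_pca` object.
#' @param tau Separation threshold (> 0, default 1.0).
#' @return Integer vector of component indices, in decreasing
#'   variance-fraction order.
#' @export
select_discriminating_pcs <- function(pca, tau = 1.0) {
  stopifnot(inherits(pca, "ale_pca"))
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  grp <- pca$isolates$group[match(rownames(pca$scores), pca$isolates$isolate_id)]
  sel <- integer(0)
  for (j in seq_len(ncol(pca$scores))) {
    s <- pca$scores[, j]
    se <- s[grp == "evolved"]; sp <- s[grp == "parental"]
    diff <- abs(mean(se) - mean(sp))
    v1 <- if (length(se) > 1) stats::var(se) else 0
    v2 <- if (length(sp) > 1) stats::var(sp) else 0
    df <- max(length(se) - 1, 0) + max(length(sp) - 1, 0)
    pooled <- if (df > 0) {
      sqrt((max(length(se) - 1, 0) * v1 + max(length(sp) - 1, 0) * v2) / df)
    } else 0
    hit <- if (pooled == 0) diff > 0 else (diff / pooled >= tau)
    if (hit) sel <- c(sel, j)
  }
  # components are already in decreasing variance_fraction order
  sel[order(pca$variance_fraction[sel], decreasing = TRUE)]
}

#' Top-contributing mutations of a principal component
#'
#' Mutations ranked by absolute loading on one component, the "most
#' contributing" mutations of that component. Ties are broken by
#' lexicographic `mutation_id`.
#'
#' @param pca An `ale_pca` object.
#' @param pc Component index.
#' @param k Number of mutations to return (default 10); capped at the number
#'   of mutations.
#' @return Character vector of mutation ids, strongest first.
#' @export
top_loadings <- function(pca, pc, k = 10) {
  stopifnot(inherits(pca, "ale_pca"))
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (pc < 1 || pc > ncol(pca$loadings)) stop("no such component: ", pc, call. = FALSE)
  l <- pca$loadings[, pc]
  ids <- rownames(pca$loadings)
  ord <- order(-abs(l), ids, method = "radix")
  ids[ord][seq_len(min(k, length(ids)))]
}

top_loading_table <- function(pca, pcs, k = 10) {
  purrr::map_dfr(pcs, function(j) {
    ids <- top_loadings(pca, j, k)
    tibble::tibble(mutation_id = ids, pc = j,
                   loading = pca$loadings[ids, j])
  })
}

#' Parental-versus-evolved frequency enrichment
#'
#' For each mutation, the arithmetic mean read-support frequency within the
#' parental and the evolved isolate group, their difference
#' (`delta = evolved - parental`), and whether the mutation increased
#' (strictly, `delta > 0`). A mutation rising between the generations is
#' marked as potentially relevant; no minimum effect size or significance
#' test is applied — this is a marking step, not a hypothesis test.
#'
#' @param fm A `freq_matrix` from [build_matrix()].
#' @return A tibble with columns `mutation_id`, `mean_parental`,
#'   `mean_evolved`, `delta`, `increasing`, in matrix row order.
#' @export
enrichment <- function(fm) {
  stopifnot(inherits(fm, "freq_matrix"))
  par_cols <- fm$isolates$isolate_id[fm$isolates$group == "parental"]
  evo_cols <- fm$isolates$isolate_id[fm$isolates$group == "evolved"]
  mp <- rowMeans(fm$mat[, par_cols, drop = FALSE])
  me <- rowMeans(fm$mat[, evo_cols, drop = FALSE])
  tibble::tibble(
    mutation_id = rownames(fm$mat),
    mean_parental = unname(mp),
    mean_evolved = unname(me),
    delta = unname(me - mp),
    increasing = unname(me - mp > 0)
  )
}

#' Gene-level exclusion of mutations in inconsistently behaving genes
#'
#' A gene containing at least one mutation at strictly decreasing frequency
#' cannot cleanly explain a gained phenotype, so all mutations in such a
#' "tainted" gene are discarded. Mutations labelled `intergenic` are never
#' removed by this rule (they are handled only by the increasing flag
#' downstream). Input order is preserved.
#'
#' @param enr An enrichment tibble from [enrichment()].
#' @param gene_map A data frame mapping `mutation_id` to `gene_id`
#'   (`"intergenic"` for mutations outside genes), e.g. from
#'   [assign_genes()].
#' @return Character vector of retained mutation ids.
#' @export
gene_exclusion_filter <- function(enr, gene_map) {
  stopifnot(is.data.frame(enr), is.data.frame(gene_map))
  if (!all(c("mutation_id", "delta") %in% names(enr))) {
    stop("`enr` needs columns mutation_id and delta", call. = FALSE)
  }
  gmap <- gene_map$gene_id[match(enr$mutation_id, gene_map$mutation_id)]
  if (any(is.na(gmap))) {
    stop("every mutation needs a gene assignment or an 'intergenic' label; missing: ",
         paste(utils::head(enr$mutation_id[is.na(gmap)], 3), collapse = ", "),
         call. = FALSE)
  }
  tainted <- unique(gmap[enr$delta < 0 & gmap != "intergenic"])
  enr$mutation_id[gmap == "intergenic" | !(gmap %in% tainted)]
}

#' Combine PCA and enrichment evidence into a ranked candidate-gene report
#'
#' Genes are candidates when they carry evidence from the loading channel
#' (at least one mutation among the top loadings of a discriminating
#' component) and/or from the enrichment channel (at least one mutation with
#' increasing frequency that survived the gene-exclusion filter). Under the
#' default `"intersection"` rule both channels are required — the two
#' supporting mutations may differ, as when one allele of a gene dominates a
#' component while another rises in frequency. Under `"union"` either
#' channel suffices. Genes are ranked by largest frequency gain, then by
#' largest absolute loading. Intergenic mutations cannot nominate a gene.
#'
#' @param pca_hits A tibble of top-loading mutations (`mutation_id`, `pc`,
#'   `loading`), e.g. from the top loadings of each selected component.
#' @param retained_increasing Character vector of mutation ids that are
#'   increasing and survived [gene_exclusion_filter()].
#' @param gene_map Mapping of `mutation_id` to `gene_id`.
#' @param enr The enrichment tibble the channels were computed from.
#' @param combine `"intersection"` (default) or `"union"`.
#' @param params Optional named list of run parameters stored in the report.
#' @return A `candidate_report`: `genes` (ranked tibble), `evidence`
#'   (per-mutation table), `params`, `status` (`"ok"` or `"empty"`).
#' @export
combine_candidates <- function(pca_hits, retained_increasing, gene_map, enr,
                               combine = c("intersection", "union"),
                               params = list()) {
  combine <- match.arg(combine)
  stopifnot(is.data.frame(gene_map), is.data.frame(enr))
  if (!is.data.frame(pca_hits)) {
    pca_hits <- tibble::tibble(mutation_id = as.character(pca_hits),
                               pc = NA_integer_, loading = NA_real_)
  }

  evidence <- enr |>
    dplyr::left_join(gene_map, by = "mutation_id") |>
    dplyr::mutate(
      top_loading = .data$mutation_id %in% pca_hits$mutation_id,
      retained_increasing = .data$mutation_id %in% retained_increasing
    )
  best_hit <- pca_hits |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::slice_max(abs(.data$loading), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("mutation_id", "pc", "loading")
  evidence <- dplyr::left_join(evidence, best_hit, by = "mutation_id")

  genic <- dplyr::filter(evidence, .data$gene_id != "intergenic")
  per_gene <- genic |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pca_channel = any(.data$top_loading),
      enrichment_channel = any(.data$retained_increasing),
      max_delta = max(.data$delta[.data$top_loading | .data$retained_increasing],
                      -Inf),
      max_abs_loading = if (any(!is.na(.data$loading))) {
        max(abs(.data$loading), na.rm = TRUE)
      } else NA_real_,
      source_pc = if (any(!is.na(.data$loading))) {
        .data$pc[which.max(ifelse(is.na(.data$loading), -1, abs(.data$loading)))]
      } else NA_integer_,
      support_mutations = paste(
        .data$mutation_id[.data$top_loading | .data$retained_increasing],
        collapse = ","),
      .groups = "drop"
    )
  keep <- if (combine == "intersection") {
    per_gene$pca_channel & per_gene$enrichment_channel
  } else {
    per_gene$pca_channel | per_gene$enrichment_channel
  }
  genes <- per_gene[keep, ] |>
    dplyr::arrange(dplyr::desc(.data$max_delta),
                   dplyr::desc(dplyr::coalesce(.data$max_abs_loading, -Inf)),
                   .data$gene_id)
  status <- if (nrow(genes) == 0) "empty" else "ok"
  if (status == "empty") {
    warning("no candidate genes under the '", combine, "' rule", call. = FALSE)
  }
  structure(list(
    genes = genes,
    evidence = evidence,
    params = utils::modifyList(list(combine = combine), params),
    status = status
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("<candidate_report> ", nrow(x$genes), " candidate gene(s), status: ",
      x$status, "\n", sep = "")
  if (nrow(x$genes) > 0) print(x$genes, ...)
  invisible(x)
}

#' @describeIn combine_candidates Ranked candidate-gene tibble.
#' @param x A `candidate_report`.
#' @param ... Unused.
#' @export
tidy.candidate_report <- function(x, ...) x$genes

#' @describeIn combine_candidates One-row run summary.
#' @export
glance.candidate_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$genes),
    n_mutations = nrow(x$evidence),
    combine = x$params$combine,
    status = x$status
  )
}

#' End-to-end mutation prioritization
#'
#' Runs the full candidate-gene identification on a table of per-isolate
#' mutation observations: frequency-matrix construction, PCA with selection
#' of parental/evolved-discriminating components and their top-`k` loadings;
#' enrichment with the gene-exclusion filter; and combination of the two
#' evidence channels into a ranked gene report.
#'
#' @param records Mutation-observation data frame (see
#'   [read_frequency_table()]).
#' @param isolates Isolate panel (`isolate_id`, `group`).
#' @param annotations Gene annotation tibble (see
#'   [read_gene_annotations()]); used to map mutation positions to genes.
#'   Alternatively pass a precomputed `gene_map`.
#' @param gene_map Optional precomputed `mutation_id` -> `gene_id` mapping;
#'   overrides `annotations`.
#' @param k Top loadings taken from each selected component (default 10).
#' @param tau Component-selection separation threshold (default 1.0).
#' @param combine Gene-level combination rule, `"intersection"` (default) or
#'   `"union"`.
#' @return A `candidate_report` (see [combine_candidates()]).
#' @export
prioritize_mutations <- function(records, isolates, annotations = NULL,
                                 gene_map = NULL, k = 10, tau = 1.0,
                                 combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  if (is.null(gene_map)) {
    if (is.null(annotations)) {
      stop("provide `annotations` or a precomputed `gene_map`", call. = FALSE)
    }
    gene_map <- assign_genes(records, annotations)
  }
  fm <- build_matrix(records, isolates)
  pca <- run_pca(fm)
  pcs <- select_discriminating_pcs(pca, tau = tau)
  hits <- top_loading_table(pca, pcs, k = k)
  enr <- enrichment(fm)
  retained <- gene_exclusion_filter(enr, gene_map)
  retained_increasing <- intersect(retained,
                                   enr$mutation_id[enr$increasing])
  combine_candidates(hits, retained_increasing, gene_map, enr,
                     combine = combine,
                     params = list(k = k, tau = tau,
                                   selected_pcs = pcs))
}
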