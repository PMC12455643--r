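#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs theme_minimal facet_wrap scale_y_continuous
NULL

#' Plot population mutation-frequency trajectories
#'
#' One line per mutation over transfers, coloured by ground-truth role;
#' drivers should sweep while most neutral standing variation is purged.
#'
#' @param object An `ale_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ale_sim <- function(object, ...) {
  df <- tidy.ale_sim(object)
  ggplot(df, aes(x = .data$transfer, y = .data$frequency,
                 group = .data$mutation_id, colour = .data$role)) +
    geom_line(alpha = 0.6) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "transfer", y = "population allele frequency",
         colour = "role",
         title = "Simulated ALE mutation trajectories") +
    theme_minimal()
}

#' Score plot of an isolate-space PCA
#'
#' Isolates plotted on the first two components, coloured by group; the
#' components that discriminate parental from evolved isolates carry the
#' candidate-mutation signal.
#'
#' @param object An `ale_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ale_pca <- function(object, ...) {
  sc <- object$scores
  df <- tibble::tibble(
    isolate_id = rownames(sc),
    PC1 = sc[, 1],
    PC2 = if (ncol(sc) >= 2) sc[, 2] else 0
  )
  df$group <- object$isolates$group[match(df$isolate_id,
                                          object$isolates$isolate_id)]
  vf <- object$variance_fraction
  lab2 <- if (length(vf) >= 2) sprintf("PC2 (%.0f%%)", 100 * vf[2]) else "PC2"
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$group)) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * vf[1]), y = lab2,
         title = "Isolate scores") +
    theme_minimal()
}

#' Evidence plot for a candidate-gene report
#'
#' Candidate genes with their maximum frequency gain (evolved minus
#' parental) and maximum absolute component loading.
#'
#' @param object A `candidate_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.candidate_report <- function(object, ...) {
  g <- object$genes
  if (nrow(g) == 0) {
    return(ggplot() + labs(title = "No candidate genes") + theme_minimal())
  }
  df <- tidyr::pivot_longer(
    g[, c("gene_id", "max_delta", "max_abs_loading")],
    cols = c("max_delta", "max_abs_loading"),
    names_to = "evidence", values_to = "value"
  )
  ggplot(df, aes(x = stats::reorder(.data$gene_id, .data$value),
                 y = .data$value)) +
    geom_col() +
    facet_wrap(~evidence, scales = "free_x") +
    labs(x = NULL, y = NULL, title = "Candidate-gene evidence") +
    theme_minimal()
}
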