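# Environment-community association: Mantel tests and correlation screens.

#' Euclidean distance between samples on standardized environmental variables
#'
#' Variables are z-scored before the distance is taken because environmental
#' measurements come in incommensurate units (pH units, mg/kg, ppm). With a
#' single variable this reduces to the absolute difference of z-scores.
#'
#' @param metadata Metadata tibble with a `sample_id` column.
#' @param variables Character vector of numeric metadata columns.
#' @return A `dist` labelled by sample id.
#' @export
env_distance <- function(metadata, variables) {
  stopifnot(length(variables) >= 1)
  missing_var <- setdiff(variables, names(metadata))
  if (length(missing_var)) {
    rlang::abort(paste0("metadata lacks variable(s): ", paste(missing_var, collapse = ", ")))
  }
  m <- as.matrix(metadata[, variables, drop = FALSE])
  if (!is.numeric(m)) rlang::abort("environmental variables must be numeric")
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- metadata$sample_id[!stats::complete.cases(m) | apply(!is.finite(m), 1, any)]
    rlang::abort(paste0("missing/non-finite values in sample(s): ",
                        paste(unique(bad), collapse = ", ")))
  }
  z <- scale(m)
  # a constant column scales to NaN; it carries no distance information
  z[, apply(m, 2, stats::sd) == 0] <- 0
  rownames(z) <- metadata$sample_id
  stats::dist(z)
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the unfolded distance matrices (Spearman by default) and
#' assesses significance by simultaneous row/column permutation of the second
#' matrix. The one-sided p-value is `(#{permuted r >= observed r} + 1) /
#' (n_perm + 1)`.
#'
#' @param dx,dy `dist` objects over the same samples.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutations.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble: `r`, `p_value`, `n_perm`, `method`.
#' @export
mantel_test <- function(dx, dy, n_perm = 9999, seed = 1L, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(n_perm >= 99)
  if (attr(dx, "Size") != attr(dy, "Size")) {
    rlang::abort("distance matrices are over different sample sets")
  }
  lx <- labels(dx); ly <- labels(dy)
  if (!is.null(lx) && !is.null(ly)) {
    if (!setequal(lx, ly)) rlang::abort("distance matrices are over different sample sets")
    if (!identical(lx, ly)) dy <- stats::as.dist(as.matrix(dy)[lx, lx])
  }
  if (stats::sd(as.vector(dx)) == 0 || stats::sd(as.vector(dy)) == 0) {
    rlang::abort("constant distance matrix: Mantel correlation undefined")
  }
  set.seed(as.integer(seed))
  mt <- vegan::mantel(dx, dy, method = method, permutations = n_perm)
  tibble::tibble(r = unname(mt$statistic), p_value = mt$signif,
                 n_perm = n_perm, method = method)
}

#' Mantel tests of a community distance against each environmental variable
#'
#' Runs [mantel_test()] of `d_community` against the standardized Euclidean
#' distance of every listed variable separately, and against all of them
#' jointly (`"all"` row), mirroring the per-variable layout of cave
#' physicochemistry Mantel tables.
#'
#' @param d_community `dist` of community dissimilarities (e.g. Bray-Curtis).
#' @param metadata Metadata tibble.
#' @param variables Numeric metadata columns to test.
#' @inheritParams mantel_test
#' @return Tibble with one row per variable plus `"all"`: `variable`, `r`,
#'   `p_value`, `n_perm`, `stars`.
#' @export
mantel_screen <- function(d_community, metadata, variables, n_perm = 9999,
                          seed = 1L, method = "spearman") {
  rows <- purrr::imap(c(stats::setNames(as.list(variables), variables),
                        list(all = variables)), function(vars, label) {
    dy <- env_distance(metadata, vars)
    res <- mantel_test(d_community, dy, n_perm = n_perm, seed = seed, method = method)
    dplyr::bind_cols(tibble::tibble(variable = label), res)
  })
  out <- dplyr::bind_rows(rows)
  out$stars <- significance_stars(out$p_value)
  out
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for 0.001 < p < 0.01, `*` for 0.01 < p < 0.05,
#' empty otherwise (the correlation-heatmap legend convention).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Pairwise correlation screen between two variable sets
#'
#' Correlates every column of `x` with every column of `y` (Spearman by
#' default) and attaches significance stars, the screen behind correlation
#' heatmaps of environmental variables against diversity indices or taxon
#' abundances. Zero-variance columns yield `NA` cells flagged `undefined`.
#'
#' @param x,y Data frames of paired numeric columns (same row order = same
#'   samples). Non-numeric columns are dropped.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble: `x_var`, `y_var`, `rho`, `p_value`, `stars`, `undefined`.
#' @export
correlation_screen <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  y <- y[, vapply(y, is.numeric, logical(1)), drop = FALSE]
  if (nrow(x) != nrow(y)) rlang::abort("x and y must be over the same samples")
  grid <- tidyr::expand_grid(x_var = names(x), y_var = names(y))
  res <- purrr::pmap(grid, function(x_var, y_var) {
    xv <- x[[x_var]]; yv <- y[[y_var]]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      return(tibble::tibble(rho = NA_real_, p_value = NA_real_, undefined = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = method, exact = FALSE))
    tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, undefined = FALSE)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$stars <- significance_stars(out$p_value)
  out[, c("x_var", "y_var", "rho", "p_value", "stars", "undefined")]
}
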