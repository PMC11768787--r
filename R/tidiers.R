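#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-fold results of a LOSO evaluation
#'
#' @param x A `pn_evaluation`.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy pn_evaluation
#' @export
tidy.pn_evaluation <- function(x, ...) {
  x$folds
}

#' Aggregate LOSO metrics
#'
#' Sensitivity and AUROC aggregate over folds whose test subject has
#' tremor windows; specificity over all folds (mirroring how the headline
#' table is formed).
#'
#' @param x A `pn_evaluation`.
#' @param ... Unused.
#' @return One-row tibble of means and SDs.
#' @method glance pn_evaluation
#' @export
glance.pn_evaluation <- function(x, ...) {
  f <- x$folds
  tremor <- f[f$n_test_tremor > 0, , drop = FALSE]
  tibble::tibble(
    model = x$config$model,
    n_folds = nrow(f),
    n_tremor_folds = nrow(tremor),
    sensitivity_mean = mean(tremor$sensitivity, na.rm = TRUE),
    sensitivity_sd = stats::sd(tremor$sensitivity),
    specificity_mean = mean(f$specificity, na.rm = TRUE),
    specificity_sd = stats::sd(f$specificity),
    auroc_mean = mean(tremor$auroc, na.rm = TRUE),
    auroc_sd = stats::sd(tremor$auroc)
  )
}

#' Tidy a prototype basis set
#'
#' @param x A `pn_basis_set`.
#' @param ... Unused.
#' @return Tibble with one row per basis (centre/scale as list-columns).
#' @method tidy pn_basis_set
#' @export
tidy.pn_basis_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.pn_basis_set
#' @method glance pn_basis_set
#' @export
glance.pn_basis_set <- function(x, ...) {
  tibble::tibble(K = attr(x, "K"), Lambda = attr(x, "Lambda"),
                 dim = length(x$center[[1L]]),
                 n_skipped = length(attr(x, "skipped")))
}

#' Tidy a fitted single-layer prototypical network
#'
#' @param x A `pn_rbf_single`.
#' @param ... Unused.
#' @return Tibble of bases with their fitted logistic weights.
#' @method tidy pn_rbf_single
#' @export
tidy.pn_rbf_single <- function(x, ...) {
  out <- tibble::as_tibble(x$basis_set)
  out$weight <- x$weights
  out
}

#' @rdname tidy.pn_rbf_single
#' @method glance pn_rbf_single
#' @export
glance.pn_rbf_single <- function(x, ...) {
  tibble::tibble(K = nrow(x$centers), intercept = x$intercept,
                 reg = x$reg, threshold = x$threshold)
}

#' Tidy a fitted two-layer prototypical network
#'
#' @param x A `pn_rbf_two_layer`.
#' @param ... Unused.
#' @return Tibble of second-layer prototype bases.
#' @method tidy pn_rbf_two_layer
#' @export
tidy.pn_rbf_two_layer <- function(x, ...) {
  tibble::as_tibble(x$C2)
}

#' @rdname tidy.pn_rbf_two_layer
#' @method glance pn_rbf_two_layer
#' @export
glance.pn_rbf_two_layer <- function(x, ...) {
  tibble::tibble(K1 = nrow(x$C1), M = x$M, K2 = nrow(x$C2_centers),
                 iterations = x$iterations %||% NA_integer_,
                 loss_initial = x$history[1L] %||% NA_real_,
                 loss_final = x$history[length(x$history)] %||% NA_real_,
                 threshold = x$threshold)
}
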