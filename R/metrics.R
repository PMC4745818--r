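#' Dice similarity coefficient between two binary masks
#'
#' \eqn{DSC = 2|S_{GT} \cap S_A| / (|S_{GT}| + |S_A|)}: 0 means no overlap,
#' 1 complete overlap. Two empty masks are defined to agree perfectly
#' (DSC 1, with a warning); empty versus nonempty is 0.
#'
#' @param pred Predicted [label_mask()] (or plain 0/1 array).
#' @param ref Reference [label_mask()] (or plain 0/1 array), same shape.
#' @return List of class `overlap_report`: `dsc`, `n_ref`, `n_pred`,
#'   `n_intersection`.
#' @export
dice <- function(pred, ref) {
  p <- if (inherits(pred, "label_mask")) pred$data else pred
  r <- if (inherits(ref, "label_mask")) ref$data else ref
  if (!identical(dim(p), dim(r)))
    stop("mask shapes differ", call. = FALSE)
  n_pred <- sum(p == 1L)
  n_ref <- sum(r == 1L)
  n_int <- sum(p == 1L & r == 1L)
  dsc <- if (n_pred + n_ref == 0L) {
    warning("both masks empty; DSC defined as 1")
    1
  } else 2 * n_int / (n_ref + n_pred)
  structure(list(dsc = dsc, n_ref = n_ref, n_pred = n_pred,
                 n_intersection = n_int),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> DSC = %.4f (ref %d, pred %d, intersection %d voxels)\n",
              x$dsc, x$n_ref, x$n_pred, x$n_intersection))
  invisible(x)
}
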