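#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  sm <- tryCatch(summary(x$model)$coefficients, error = function(e) NULL)
  tibble(
    term = c("bottom", "top", "ec50", "hill"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill),
    std.error = if (is.null(sm)) NA_real_ else sm[c("bottom", "top", "ec50", "hill"), "Std. Error"]
  )
}

#' @rdname tidy.dose_response_fit
#' @return For `glance()`: a one-row fit summary (`rss`, `converged`, `n`).
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n = x$n)
}

#' Tidy a chimera design
#'
#' @param x A `chimera_design`.
#' @param ... Unused.
#' @return `tidy()`: the per-residue provenance tibble. `glance()`: a one-row
#'   summary with chimera id, length, block count and rule set.
#' @export
tidy.chimera_design <- function(x, ...) x$provenance

#' @rdname tidy.chimera_design
#' @export
glance.chimera_design <- function(x, ...) {
  tibble(
    id = x$chimera$id,
    length = seq_length(x$chimera),
    n_blocks = nrow(provenance_blocks(x)),
    n_target_residues = sum(x$provenance$source == "TARGET"),
    ruleset = x$ruleset$name,
    backbone_id = x$inputs$backbone_id,
    target_id = x$inputs$target_id
  )
}
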