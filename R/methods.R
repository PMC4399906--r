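#' The GWSS method registry
#'
#' Each named member of the generalized weighted-sum statistic family is a
#' triple: a weight scheme (Step 1), a summary measure (Step 2), and a
#' threshold mode (Step 3). The ten standard names are:
#'
#' | name      | weight | summary  | threshold       |
#' |-----------|--------|----------|-----------------|
#' | WSS       | MAF    | rank-sum | fixed           |
#' | ORWSS     | OR     | rank-sum | fixed           |
#' | WSS-t     | MAF    | t-sum    | fixed           |
#' | ORWSS-t   | OR     | t-sum    | fixed           |
#' | DSS-t     | D      | t-sum    | fixed           |
#' | DWSS-t    | DW     | t-sum    | fixed           |
#' | VWSS-t    | MAF    | t-sum    | sup over thetas |
#' | VORWSS-t  | OR     | t-sum    | sup over thetas |
#' | VDSS-t    | D      | t-sum    | sup over thetas |
#' | VDWSS-t   | DW     | t-sum    | sup over thetas |
#'
#' "V" prefixes take the maximum of the statistic over a set of candidate
#' MAF thresholds (variable-threshold idea); non-V methods evaluate at a
#' single fixed threshold, by default `Inf` (no MAF filter, all variants
#' contribute).
#'
#' @return `gwss_methods()` returns a data frame listing the registry.
#' @export
gwss_methods <- function() {
  data.frame(
    name = c("WSS", "ORWSS", "WSS-t", "ORWSS-t", "DSS-t", "DWSS-t",
             "VWSS-t", "VORWSS-t", "VDSS-t", "VDWSS-t"),
    weight = c("MAF", "OR", "MAF", "OR", "D", "DW", "MAF", "OR", "D", "DW"),
    summary = c("rank-sum", "rank-sum", rep("t-sum", 8)),
    threshold = c(rep("fixed", 6), rep("sup", 4)),
    stringsAsFactors = FALSE
  )
}

#' Resolve a GWSS method specification
#'
#' @param method either one of the registry names of [gwss_methods()], or a
#'   list with elements `weight` (`"MAF"`, `"OR"`, `"D"`, `"DW"`),
#'   `summary` (`"rank-sum"`, `"t-sum"`) and `threshold` (`"fixed"` or
#'   `"sup"`) for a custom combination.
#' @param theta MAF threshold for fixed mode; `Inf` (default) disables the
#'   filter so every variant contributes. Ignored in sup mode.
#' @param theta_set candidate threshold set for sup mode: `"observed"`
#'   (default; the sorted unique adjusted control MAFs of the data at hand,
#'   the finest data-driven grid) or a numeric vector of thresholds.
#' @return object of class `gwss_method`: list with `name`, `weight`,
#'   `summary`, `threshold`, `theta`, `theta_set`.
#' @examples
#' gwss_method("VDWSS-t")
#' gwss_method(list(weight = "DW", summary = "rank-sum", threshold = "sup"))
#' @export
gwss_method <- function(method, theta = Inf, theta_set = "observed") {
  if (inherits(method, "gwss_method")) return(method)
  if (is.character(method) && length(method) == 1L) {
    reg <- gwss_methods()
    i <- match(method, reg$name)
    if (is.na(i)) {
      stop("unknown GWSS method '", method, "'; see gwss_methods() for the registry")
    }
    spec <- list(name = reg$name[i], weight = reg$weight[i],
                 summary = reg$summary[i], threshold = reg$threshold[i])
  } else if (is.list(method)) {
    spec <- list(
      name = if (!is.null(method$name)) method$name else "custom",
      weight = match.arg(method$weight, c("MAF", "OR", "D", "DW")),
      summary = match.arg(method$summary, c("rank-sum", "t-sum")),
      threshold = match.arg(method$threshold, c("fixed", "sup"))
    )
  } else {
    stop("method must be a registry name or a list(weight=, summary=, threshold=)")
  }
  if (spec$threshold == "fixed") {
    if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
      stop("fixed-threshold mode needs a single theta > 0 (use Inf for no filter)")
    }
  }
  if (is.numeric(theta_set)) {
    if (length(theta_set) < 1L) stop("theta_set grid must be nonempty")
    theta_set <- sort(unique(theta_set))
  } else {
    theta_set <- match.arg(theta_set, "observed")
  }
  structure(c(spec, list(theta = theta, theta_set = theta_set)),
            class = "gwss_method")
}

#' @export
print.gwss_method <- function(x, ...) {
  thr <- if (x$threshold == "fixed") {
    sprintf("fixed theta = %s", format(x$theta))
  } else if (is.character(x$theta_set)) {
    "sup over observed adjusted MAFs"
  } else {
    sprintf("sup over %d user thresholds", length(x$theta_set))
  }
  cat(sprintf("GWSS method '%s': %s weight, %s summary, %s\n",
              x$name, x$weight, x$summary, thr))
  invisible(x)
}
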