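#' Cost matrices for triage misallocation
#'
#' A cost matrix is a 3x3 nonnegative matrix `C[true, predicted]` over the
#' WARD/IMC/ICU classes. Three kinds exist: the relative resource-cost
#' matrix RC built from nurse-to-patient staffing ratios, the harm-cost
#' matrix HC built from inverse class frequencies, and their zeta-weighted
#' combination used for training and decision-making.
#'
#' @param entries 3x3 numeric matrix, rows = true class, cols = predicted.
#' @param kind one of `"RC"`, `"HC"`, `"combined"`.
#' @param zeta the combination weight (combined matrices only).
#' @param provenance optional list recording the ratios/frequencies the
#'   matrix was built from.
#' @return a `cost_matrix` object.
#' @export
cost_matrix <- function(entries, kind = c("combined", "RC", "HC"),
                        zeta = NULL, provenance = NULL) {
  kind <- match.arg(kind)
  entries <- as.matrix(entries)
  if (!all(dim(entries) == c(3L, 3L))) stop("cost matrix must be 3x3")
  if (!all(is.finite(entries)) || any(entries < 0)) {
    stop("cost matrix entries must be finite and nonnegative")
  }
  dimnames(entries) <- list(true = names(triage_levels()),
                            predicted = names(triage_levels()))
  structure(entries, class = c("cost_matrix", "matrix"),
            kind = kind, zeta = zeta, provenance = provenance)
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix kind=%s%s>\n", attr(x, "kind"),
              if (!is.null(attr(x, "zeta")))
                sprintf(" zeta=%g", attr(x, "zeta")) else ""))
  print(unclass(structure(x, kind = NULL, zeta = NULL, provenance = NULL)))
  invisible(x)
}

#' Relative resource-cost matrix from staffing ratios
#'
#' Nurse-to-patient ratios (default ward 10:1, IMC 4:1, ICU 2:1) are a
#' transparent proxy for relative nursing resource intensity: the intensity
#' of the assigned level j is `r_j = 1 / ratio_j`, and
#' `RC[i, j] = r_j / sum_k r_k` for every true class i. The allocation cost
#' depends only on the assigned level, so it applies on- and off-diagonal
#' (a correct ICU assignment still consumes ICU staffing); rows sum to 1.
#'
#' @param nurse_ratios positive 3-vector of patients per nurse for
#'   ward/IMC/ICU.
#' @return a `cost_matrix` of kind RC.
#' @export
#' @examples
#' build_rc()  # each row (0.1, 0.25, 0.5) / 0.85
build_rc <- function(nurse_ratios = c(10, 4, 2)) {
  stopifnot(length(nurse_ratios) == 3)
  if (any(!is.finite(nurse_ratios)) || any(nurse_ratios <= 0)) {
    stop("nurse ratios must be positive")
  }
  r <- 1 / nurse_ratios
  row <- r / sum(r)
  cost_matrix(matrix(row, 3, 3, byrow = TRUE), kind = "RC",
              provenance = list(nurse_ratios = nurse_ratios))
}

#' Harm-cost matrix from inverse class frequencies
#'
#' Penalizes under-triage (predicted level below the true one) with weights
#' proportional to the inverse frequency of the true class, so that missing
#' a rare high-acuity patient is costliest. Scaled so the maximum entry is
#' 1, making the zeta weight comparable across cohorts with different class
#' priors: `HC[i, j] = (1/freq_i) / max_k (1/freq_k)` for `j < i`, else 0.
#'
#' @param class_freq probability 3-vector of ward/IMC/ICU frequencies,
#'   all positive.
#' @return a `cost_matrix` of kind HC.
#' @export
#' @examples
#' build_hc(c(0.629, 0.247, 0.124))
build_hc <- function(class_freq) {
  stopifnot(length(class_freq) == 3)
  if (any(!is.finite(class_freq)) || any(class_freq <= 0)) {
    stop("class frequencies must be strictly positive")
  }
  if (abs(sum(class_freq) - 1) > 1e-6) {
    stop("class frequencies must sum to 1")
  }
  w <- (1 / class_freq) / max(1 / class_freq)
  hc <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) if (j < i) hc[i, j] <- w[i]
  cost_matrix(hc, kind = "HC",
              provenance = list(class_frequencies = class_freq))
}

#' Combine resource and harm costs with weight zeta
#'
#' `C(zeta) = exp(-zeta) * RC + exp(zeta) * HC`, normalized by its maximum
#' entry. Negative zeta makes the resource term dominate (at zeta = -5 the
#' cheapest assignment for every patient is the ward); positive zeta makes
#' the under-triage harm term dominate (escalation toward ICU). The
#' exponential weighting is smooth, symmetric about zeta = 0, and spans the
#' full regime change over zeta in [-5, 5]; it is isolated here so an
#' alternative combination rule is a drop-in replacement.
#'
#' @param rc a `cost_matrix` of kind RC.
#' @param hc a `cost_matrix` of kind HC.
#' @param zeta finite scalar.
#' @return a `cost_matrix` of kind combined with attribute `zeta`.
#' @export
combine_cost <- function(rc, hc, zeta) {
  stopifnot(inherits(rc, "cost_matrix"), inherits(hc, "cost_matrix"))
  if (attr(rc, "kind") != "RC" || attr(hc, "kind") != "HC") {
    stop("combine_cost expects an RC and an HC matrix, in that order")
  }
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta)) {
    stop("zeta must be a finite scalar")
  }
  m <- exp(-zeta) * unclass(rc) + exp(zeta) * unclass(hc)
  cost_matrix(m / max(m), kind = "combined", zeta = zeta,
              provenance = list(rc = attr(rc, "provenance"),
                                hc = attr(hc, "provenance")))
}

#' Serialize / deserialize a cost matrix as JSON
#'
#' @param x a `cost_matrix`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly the path when written to file).
#' @export
cost_matrix_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cost_matrix"))
  obj <- list(entries = unclass(structure(x, kind = NULL, zeta = NULL,
                                          provenance = NULL,
                                          class = NULL)),
              kind = attr(x, "kind"),
              zeta = attr(x, "zeta"),
              provenance = attr(x, "provenance"))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname cost_matrix_to_json
#' @param json JSON string or file path produced by [cost_matrix_to_json()].
#' @export
cost_matrix_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cost_matrix(matrix(unlist(obj$entries), 3, 3), kind = obj$kind,
              zeta = obj$zeta, provenance = obj$provenance)
}
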