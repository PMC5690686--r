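#' Ratio of Concordance Preference
#'
#' The RCP statistic \eqn{2\sqrt{MU}/H}, the ratio of observed
#' concordance between the two strands of CpG/CpG dyads to the
#' expectation under random placement of methyl groups. Equivalently, in
#' the (m, U) parameterization with overall methylation frequency
#' \eqn{m = M + H/2}, \eqn{RCP = \sqrt{U(U + 2m - 1)}/(1 - U - m)}, and
#' \eqn{RCP^2 = 4MU/H^2}, the classical Hardy-Weinberg disequilibrium
#' ratio for genotype-style frequencies. RCP = 1 under random placement,
#' > 1 under conservative (concordance-preferring) systems, < 1 under
#' dispersive systems.
#'
#' `rcp` returns `+Inf` for complete concordance preference (H = 0 with
#' M > 0 and U > 0) and `0` for complete discordance preference (M = 0
#' or U = 0 with H > 0). For completely methylated or unmethylated
#' regions (m = 0 or m = 1) RCP cannot be inferred and an error is
#' raised.
#'
#' @param x a [DyadFreqs-class], a [DyadCounts-class], or a numeric
#'   vector `c(M, H, U)` of dyad-state frequencies or counts.
#' @param ... unused.
#' @return A single non-negative number, possibly `Inf`.
#' @examples
#' rcp(dyadFreqs(0.25, 0.5, 0.25)) # random placement -> 1
#' rcp(c(1, 1, 1) / 3)             # 2-fold concordance preference
#' rcp(dyadCounts(40, 20, 40))     # plug-in from counts -> 4
#' @export
setGeneric("rcp", function(x, ...) standardGeneric("rcp"))

#' @rdname DyadCounts-class
#' @param object,x a `DyadCounts` object.
#' @export
setGeneric("asFreqs", function(x, ...) standardGeneric("asFreqs"))

#' @name accessors
#' @title Accessors for rcpmeth S4 objects
#' @description Read-only accessors for the slots of the value classes:
#'   estimate and interval components of [RcpEstimate-class], statistic
#'   and p-value of [TestResult-class], and the count cells of
#'   [DyadCounts-class].
#' @param x an rcpmeth S4 object.
#' @return The corresponding slot value.
#' @examples
#' est <- likelihoodCi(dyadCounts(40, 20, 40))
#' point(est)
#' ciLimits(est)
NULL

#' @rdname accessors
#' @export
setGeneric("point", function(x) standardGeneric("point"))

#' @rdname accessors
#' @export
setGeneric("pointBc", function(x) standardGeneric("pointBc"))

#' @rdname accessors
#' @export
setGeneric("ciLimits", function(x) standardGeneric("ciLimits"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname accessors
#' @export
setGeneric("flags", function(x) standardGeneric("flags"))
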