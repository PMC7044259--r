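#' @useDynLib oleoflux, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# low-level LP interface: min/max c'v s.t. A v = b, lb <= v <= ub.
# Returns list(status, x, objective). Kept internal; fba() is the public face.
solveLP <- function(A, b, c, lb, ub, maximize = TRUE) {
  stopifnot(length(b) == nrow(A), length(c) == ncol(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  .simplexSolve(as.matrix(A), as.numeric(b), as.numeric(c),
                as.numeric(lb), as.numeric(ub), isTRUE(maximize))
}

# assemble the FBA constraint data from a model
lpData <- function(model) {
  list(A = as.matrix(model@S),
       b = numeric(nrow(model@S)),
       lb = model@reactions$lowerBound,
       ub = model@reactions$upperBound,
       ids = model@reactions$id)
}

objectiveVector <- function(model, objective) {
  ids <- model@reactions$id
  cvec <- numeric(length(ids))
  names(cvec) <- ids
  if (is.null(objective)) objective <- model@objective
  if (is.null(names(objective)) || !all(names(objective) %in% ids))
    stop("objective must be a named vector of existing reaction ids")
  cvec[names(objective)] <- objective
  cvec
}

#' @describeIn fba Solve FBA on a model.
#' @param objective named numeric of objective weights per reaction id;
#'   default the model's stored objective (usually the biomass reaction).
#' @param direction \code{"max"} or \code{"min"}.
#' @examples
#' sol <- fba(buildToyGEM())
#' sol@objectiveValue     # growth rate on glycerol, 1/h
#' @export
setMethod("fba", "MetabolicModel",
  function(model, objective = NULL, direction = c("max", "min")) {
    direction <- match.arg(direction)
    d <- lpData(model)
    cvec <- objectiveVector(model, objective)
    r <- solveLP(d$A, d$b, cvec, d$lb, d$ub, maximize = direction == "max")
    if (r$status != "optimal") {
      if (r$status == "numerical")
        stop("LP solver failed numerically on this model")
      return(new("FluxDistribution", fluxes = numeric(),
                 objectiveValue = NA_real_, status = r$status))
    }
    new("FluxDistribution",
        fluxes = stats::setNames(as.numeric(r$x), d$ids),
        objectiveValue = r$objective, status = "optimal")
  })

#' @describeIn fluxVariability Per-reaction min/max flux under the model
#'   constraints, optionally requiring the stored objective to stay at or
#'   above \code{fractionOfOptimum} times its optimum.
#' @param fractionOfOptimum numeric in [0, 1], or NULL for no objective
#'   constraint.
#' @param reactions reaction ids to analyze (default all).
#' @export
setMethod("fluxVariability", "MetabolicModel",
  function(model, fractionOfOptimum = NULL, reactions = NULL) {
    d <- lpData(model)
    A <- d$A; b <- d$b; lb <- d$lb; ub <- d$ub
    if (!is.null(fractionOfOptimum)) {
      stopifnot(fractionOfOptimum >= 0, fractionOfOptimum <= 1)
      opt <- fba(model)
      if (opt@status != "optimal")
        stop("model is ", opt@status, "; cannot run FVA")
      cvec <- objectiveVector(model, NULL)
      # c'v - s = 0 with s >= fraction * optimum encodes the objective floor
      A <- rbind(cbind(A, 0), c(cvec, -1))
      b <- c(b, 0)
      lo <- fractionOfOptimum * opt@objectiveValue
      lb <- c(lb, min(lo, opt@objectiveValue))
      ub <- c(ub, max(abs(opt@objectiveValue) * 2 + 1, 1e4))
    } else {
      probe <- solveLP(A, b, numeric(ncol(A)), lb, ub)
      if (probe$status != "optimal") stop("model is ", probe$status)
    }
    if (is.null(reactions)) reactions <- d$ids
    idx <- match(reactions, d$ids)
    if (anyNA(idx)) stop("unknown reaction id(s)")
    n <- ncol(A)
    res <- vapply(idx, function(j) {
      cv <- numeric(n); cv[j] <- 1
      lo <- solveLP(A, b, cv, lb, ub, maximize = FALSE)
      hi <- solveLP(A, b, cv, lb, ub, maximize = TRUE)
      if (lo$status != "optimal" || hi$status != "optimal")
        stop("FVA subproblem not optimal for ", d$ids[j])
      c(lo$objective, hi$objective)
    }, numeric(2))
    new("FluxRange", ranges = data.frame(id = reactions,
                                         min = pmin(res[1, ], res[2, ]),
                                         max = pmax(res[1, ], res[2, ])))
  })

#' @describeIn sampleFluxes Vertex sampling with random objectives: each
#'   sample maximizes a random-signed, random-weighted objective over all
#'   reactions, characterizing the feasible solution space by its vertices.
#'   Random weights are assigned by reaction id (in sorted-id order), so a
#'   reordering of the reaction table permutes sample columns without
#'   changing the sampled solutions.
#' @param n number of samples (> 0).
#' @param seed integer seed; the sample is reproducible from it.
#' @export
setMethod("sampleFluxes", "MetabolicModel",
  function(model, n = 5000, seed = 1L) {
    if (!is.numeric(n) || n <= 0) stop("n must be a positive integer")
    n <- as.integer(n)
    d <- lpData(model)
    probe <- solveLP(d$A, d$b, numeric(length(d$ids)), d$lb, d$ub)
    if (probe$status != "optimal")
      stop("model is ", probe$status, "; cannot sample")
    ord <- order(d$ids)
    M <- matrix(NA_real_, n, length(d$ids), dimnames = list(NULL, d$ids))
    set.seed(as.integer(seed))
    for (i in seq_len(n)) {
      cvec <- numeric(length(d$ids))
      cvec[ord] <- stats::rnorm(length(d$ids))
      r <- solveLP(d$A, d$b, cvec, d$lb, d$ub, maximize = TRUE)
      if (r$status != "optimal")
        stop("sampling LP not optimal (status ", r$status, ")")
      M[i, ] <- r$x
    }
    new("FluxSample", matrix = M, seed = as.integer(seed), n = n)
  })

#' Summarize a flux sample
#'
#' @param x a \code{\link{FluxSample}}.
#' @param probs quantiles to report.
#' @return data.frame with per-reaction mean and quantiles.
#' @export
summarizeFluxSample <- function(x, probs = c(0.025, 0.975)) {
  M <- x@matrix
  q <- t(apply(M, 2, stats::quantile, probs = probs))
  out <- data.frame(id = colnames(M), mean = colMeans(M))
  for (k in seq_along(probs)) out[[paste0("q", probs[k])]] <- q[, k]
  rownames(out) <- NULL
  out
}
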