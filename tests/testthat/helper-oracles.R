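# Independent oracles and small fixtures used across the suite.

# Brute-force LP oracle: enumerate candidate vertices of
# {v : S v = 0, lb <= v <= ub} by choosing rank(S) "free" columns and pinning
# the rest at a bound, then take the best feasible candidate. Exponential,
# fine for <= 8 reactions. Completely independent of the package solver.
enumerateLP <- function(S, lb, ub, cc, maximize = TRUE, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  best <- NULL
  bestObj <- if (maximize) -Inf else Inf
  freeSets <- if (r == 0) list(integer(0)) else
    asplit(utils::combn(n, r), 2)
  for (Fset in freeSets) {
    Fset <- as.integer(Fset)
    SF <- S[, Fset, drop = FALSE]
    if (qr(SF)$rank < r) next
    Nset <- setdiff(seq_len(n), Fset)
    # rows: use a maximal independent row subset of SF
    qrf <- qr(t(SF))
    rows <- qrf$pivot[seq_len(r)]
    nN <- length(Nset)
    for (mask in seq_len(2^nN) - 1L) {
      vN <- numeric(nN)
      for (k in seq_len(nN)) {
        atUB <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0
        vN[k] <- if (atUB) ub[Nset[k]] else lb[Nset[k]]
      }
      if (nN && any(!is.finite(vN))) next
      rhs <- if (nN) -S[rows, Nset, drop = FALSE] %*% vN else numeric(r)
      vF <- tryCatch(solve(S[rows, Fset, drop = FALSE], rhs),
                     error = function(e) NULL)
      if (is.null(vF)) next
      v <- numeric(n)
      v[Fset] <- vF
      v[Nset] <- vN
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (max(abs(S %*% v)) > tol) next
      obj <- sum(cc * v)
      if ((maximize && obj > bestObj) || (!maximize && obj < bestObj)) {
        bestObj <- obj
        best <- v
      }
    }
  }
  list(objective = bestObj, v = best, feasible = !is.null(best))
}

# a linear chain A_ex -> A -> B -> B_ex as a MetabolicModel; bounds settable
chainModel <- function(convUB = 10, exAUB = 5) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", formula = c("C1", "C1"), charge = 0L)
  rxns <- data.frame(id = c("EX_A", "CONV", "EX_B", "GROW"),
                     name = c("A uptake", "A to B", "B export", "growth"),
                     lowerBound = c(-exAUB, 0, 0, 0),
                     upperBound = c(0, convUB, 1000, 0),
                     subsystem = "")
  S <- matrix(0, 2, 4, dimnames = list(mets$id, rxns$id))
  S["A", "EX_A"] <- -1; S["A", "CONV"] <- -1
  S["B", "CONV"] <- 1; S["B", "EX_B"] <- -1
  MetabolicModel(mets, rxns, S, biomassId = "GROW",
                 objective = c(EX_B = 1))
}

# random small flux networks for oracle-equivalence tests
randomSmallModel <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1)
  n <- m + sample(2:4, 1)
  repeat {
    S <- matrix(sample(c(-1, 0, 0, 1), m * n, replace = TRUE), m, n)
    if (all(colSums(S != 0) > 0)) break
  }
  lb <- ifelse(stats::runif(n) < 0.4, -stats::runif(n, 0, 5), 0)
  ub <- lb + stats::runif(n, 0.5, 8)
  ids <- paste0("R", seq_len(n))
  mets <- data.frame(id = paste0("M", seq_len(m)), name = "",
                     compartment = "c", formula = NA_character_, charge = 0L)
  rxns <- data.frame(id = ids, name = ids, lowerBound = lb, upperBound = ub,
                     subsystem = "")
  dimnames(S) <- list(mets$id, ids)
  MetabolicModel(mets, rxns, S, biomassId = ids[1],
                 objective = stats::setNames(stats::rnorm(n), ids))
}

maxAbsMassViolation <- function(model, v) {
  max(abs(as.matrix(stoichiometry(model)) %*% v[reactions(model)$id]))
}

# closed-form theoretical lipid carbon yields of the default toy network,
# derived by hand from carbon/NADPH/ATP accounting (see the methods
# vignette for the derivations)
toyYieldOracle <- c(glycerol = 11 / 16, xylose = 23 / 40, acetate = 9 / 23)
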