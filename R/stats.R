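#' Pearson correlation with least-squares regression line
#'
#' The product-moment correlation coefficient `r`, its two-tailed p-value
#' from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, and the least-squares line `y = intercept + slope*x`.
#' The line always passes through the sample means. `p = 1` exactly when
#' `r = 0`, and `p = 0` for exact linear dependence.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, both non-constant.
#' @return named list: `r`, `p`, `slope`, `intercept`, `n`, `equation`
#'   (formatted line, two decimals, ASCII minus).
#' @export
pearsonWithRegression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0) stop("zero variance in x")
  if (sy == 0) stop("zero variance in y")
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  r <- sxy / (sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  slope <- sxy / sx^2
  intercept <- mean(y) - slope * mean(x)
  list(r = r, p = p, slope = slope, intercept = intercept, n = n,
       equation = formatRegressionEquation(intercept, slope))
}

#' Format a regression line as an equation string
#'
#' `y = a + bx` with two decimals and an ASCII hyphen for negative slopes,
#' e.g. `"y = 34.54 - 0.15x"`.
#'
#' @param intercept,slope coefficients of the line.
#' @return character scalar.
#' @export
formatRegressionEquation <- function(intercept, slope) {
  sprintf("y = %.2f %s %.2fx", intercept, ifelse(slope < 0, "-", "+"),
          abs(slope))
}

#' Evaluate a regression line
#'
#' @param intercept,slope coefficients of the line `y = intercept + slope*x`.
#' @param x value(s) at which to evaluate.
#' @return `intercept + slope * x`.
#' @export
evaluateRegression <- function(intercept, slope, x) intercept + slope * x

#' Candidate-correlation bookkeeping
#'
#' The number of candidate correlations in a screen: scanning planes x
#' echotexture variables per plane x traits x groups (use `nGroups = 1`
#' for a pooled screen). For the reference design this gives
#' `4 * 2 * 26 * 3 = 624` within-group and `4 * 2 * 26 * 1 = 208` pooled
#' candidates.
#'
#' @param nPlanes,nEchoVars,nTraits,nGroups positive integer counts.
#' @return the product, as integer.
#' @export
countCandidates <- function(nPlanes = 4, nEchoVars = 2, nTraits = 26,
                            nGroups = 3) {
  counts <- c(nPlanes, nEchoVars, nTraits, nGroups)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  as.integer(nPlanes * nEchoVars * nTraits * nGroups)
}

#' Guilford strength label for a correlation coefficient
#'
#' Conventional verbal bands on |r|: below 0.2 "slight", 0.2 to 0.4 "low",
#' 0.4 to 0.7 "moderate", 0.7 to 0.9 "high", 0.9 and above "very high".
#' Band edges are configurable (some authors verbally label borderline
#' values differently); intervals are closed on the left.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param bands increasing upper edges of the first four bands.
#' @return character vector of labels.
#' @export
strengthLabel <- function(r, bands = c(0.2, 0.4, 0.7, 0.9)) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  stopifnot(length(bands) == 4, !is.unsorted(bands))
  labs <- c("slight", "low", "moderate", "high", "very high")
  labs[findInterval(abs(r), bands) + 1L]
}

## vectorized screen core for one stratum: X (n x p echo), Y (n x q traits)
screenStratum <- function(X, Y, groupLabel, alpha) {
  n <- nrow(X)
  keepX <- apply(X, 2, stats::sd) > 0
  keepY <- apply(Y, 2, stats::sd) > 0
  skipVars <- c(colnames(X)[!keepX], colnames(Y)[!keepY])
  skipped <- data.frame(
    group = rep(groupLabel, length(skipVars)), variable = skipVars,
    reason = rep("zero variance", length(skipVars)),
    stringsAsFactors = FALSE)
  X <- X[, keepX, drop = FALSE]; Y <- Y[, keepY, drop = FALSE]
  if (ncol(X) == 0 || ncol(Y) == 0)
    return(list(rows = NULL, skipped = skipped))
  R <- stats::cor(X, Y)
  R[R > 1] <- 1; R[R < -1] <- -1
  sx <- apply(X, 2, stats::sd); sy <- apply(Y, 2, stats::sd)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  slope <- R * outer(1 / sx, sy)
  intercept <- outer(rep(1, ncol(X)), ybar) - slope * xbar
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(R) >= 1] <- 0
  p[R == 0] <- 1
  rows <- data.frame(
    group = groupLabel,
    input_variable = rep(colnames(X), times = ncol(Y)),
    output_variable = rep(colnames(Y), each = ncol(X)),
    r = as.vector(R), p_value = as.vector(p),
    slope = as.vector(slope), intercept = as.vector(intercept),
    n = n, stringsAsFactors = FALSE)
  rows$equation <- formatRegressionEquation(rows$intercept, rows$slope)
  rows$strength_label <- strengthLabel(rows$r)
  rows$significant <- rows$p_value < alpha
  list(rows = rows, skipped = skipped)
}

echoToWide <- function(echo) {
  ids <- unique(echo[, c("bird_id", "group")])
  X <- matrix(NA_real_, nrow(ids), 8,
              dimnames = list(ids$bird_id,
                              as.vector(t(outer(VALID_PLANES, c("MPI", "MPH"),
                                                paste, sep = "-")))))
  for (k in seq_len(nrow(echo))) {
    i <- match(echo$bird_id[k], ids$bird_id)
    X[i, paste0(echo$plane[k], "-MPI")] <- echo$mpi[k]
    X[i, paste0(echo$plane[k], "-MPH")] <- echo$mph[k]
  }
  complete <- rowSums(is.na(X)) == 0
  if (!any(complete))
    stop("no bird has complete plane coverage (all four planes are required)")
  if (!all(complete))
    message(sum(!complete), " bird(s) without complete plane coverage ",
            "dropped from the screen: ",
            paste(ids$bird_id[!complete], collapse = ", "))
  list(X = X[complete, , drop = FALSE],
       ids = ids[complete, , drop = FALSE],
       dropped = ids$bird_id[!complete])
}

#' Pearson correlation screen of echotexture variables against traits
#'
#' Correlates every plane-prefixed echotexture variable (L/T/O1/O2 x
#' MPI/MPH) with every trait column, within each group or pooled across
#' all birds, and reports the candidate bookkeeping: `possible` from
#' [countCandidates()] with the nominal trait count, the number of pairs
#' actually tested (constant columns within a stratum are skipped with a
#' notice), the number significant at `alpha`, and the percentage
#' `100 * significant / possible` rounded to one decimal.
#'
#' @param echo long echotexture records (`bird_id`, `group`, `plane`,
#'   `mpi`, `mph`), e.g. from [analyzeBatch()] or [simulateTraitTable()].
#' @param traits wide trait table (`bird_id`, `group`, one column per
#'   trait).
#' @param alpha significance threshold (default 0.05).
#' @param pooled `FALSE` for the within-group screen, `TRUE` to pool all
#'   birds into a single stratum.
#' @param nTraitsNominal nominal trait count for the candidate bookkeeping
#'   (default 26, the reference study's published enumeration; the shipped
#'   trait table has 29 columns).
#' @param bhAnnotation add a Benjamini-Hochberg adjusted p-value column
#'   (`p_adj_bh`) as an annotation; the screen itself always selects on the
#'   raw p-values.
#' @return a [ScreenResult-class].
#' @export
correlationScreen <- function(echo, traits, alpha = 0.05, pooled = FALSE,
                              nTraitsNominal = 26, bhAnnotation = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  ew <- echoToWide(echo)
  traitCols <- setdiff(names(traits), c("bird_id", "group"))
  ## birds dropped for incomplete plane coverage may still carry trait rows
  unmatched <- c(setdiff(ew$ids$bird_id, traits$bird_id),
                 setdiff(traits$bird_id, c(ew$ids$bird_id, ew$dropped)))
  if (length(unmatched))
    stop("bird_ids do not match between echotexture and trait tables: ",
         paste(unique(unmatched), collapse = ", "))
  Y <- as.matrix(traits[match(ew$ids$bird_id, traits$bird_id), traitCols,
                        drop = FALSE])
  rownames(Y) <- ew$ids$bird_id

  strata <- if (pooled) list(POOLED = seq_len(nrow(ew$X))) else
    split(seq_len(nrow(ew$X)), ew$ids$group)
  allRows <- list(); allSkipped <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (length(idx) < 3)
      stop("stratum '", s, "' has fewer than 3 birds")
    st <- screenStratum(ew$X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                        s, alpha)
    allRows[[s]] <- st$rows
    allSkipped[[s]] <- st$skipped
  }
  results <- do.call(rbind, allRows)
  if (is.null(results))
    results <- data.frame(group = character(), input_variable = character(),
                          output_variable = character(), r = numeric(),
                          p_value = numeric(), slope = numeric(),
                          intercept = numeric(), n = integer(),
                          equation = character(), strength_label = character(),
                          significant = logical())
  rownames(results) <- NULL
  skipped <- do.call(rbind, allSkipped)
  rownames(skipped) <- NULL
  if (nrow(skipped) > 0)
    message(nrow(skipped),
            " zero-variance variable/group combination(s) skipped in the screen")
  if (bhAnnotation && nrow(results) > 0)
    results$p_adj_bh <- stats::p.adjust(results$p_value, method = "BH")
  possible <- countCandidates(nTraits = nTraitsNominal,
                              nGroups = if (pooled) 1L else length(strata))
  nSig <- sum(results$significant)
  new("ScreenResult", results = results, alpha = alpha,
      possible = possible, performed = nrow(results),
      nSignificant = as.integer(nSig),
      percentage = round(100 * nSig / possible, 1),
      pooled = pooled, skipped = skipped)
}

#' Screen percentage bookkeeping
#'
#' `100 * significant / possible`, rounded to one decimal — the convention
#' used when summarizing how many of the candidate correlations reached
#' significance (e.g. 19 of 624 -> 3.0, 12 of 208 -> 5.8).
#'
#' @param significant,possible counts.
#' @return percentage rounded to one decimal.
#' @export
screenPercentage <- function(significant, possible) {
  if (possible < 1 || significant < 0 || significant > possible)
    stop("need 0 <= significant <= possible, possible >= 1")
  round(100 * significant / possible, 1)
}

## compact letter display by insert-and-absorb over the significance matrix;
## levels ordered by decreasing mean so "a" attaches to the largest mean
compactLetters <- function(levelsOrdered, sigPairs) {
  sets <- list(levelsOrdered)
  for (k in seq_len(nrow(sigPairs))) {
    a <- sigPairs$level1[k]; b <- sigPairs$level2[k]
    newSets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        newSets <- c(newSets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        newSets <- c(newSets, list(s))
      }
    }
    ## absorb subsets
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets)) for (j in seq_along(newSets)) {
      if (i != j && keep[i] && keep[j] &&
          all(newSets[[i]] %in% newSets[[j]]) &&
          (length(newSets[[i]]) < length(newSets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- newSets[keep]
  }
  ord <- order(vapply(sets, function(s) match(s[1], levelsOrdered), 1L))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(levelsOrdered)), levelsOrdered)
  for (i in seq_along(sets))
    for (lv in sets[[i]])
      out[lv] <- paste0(out[lv], letters[i])
  out
}

anovaGuardDegenerate <- function(y, groupsList) {
  ## returns NULL normally; a list(F, p) when residual variance is zero
  mse0 <- sum(vapply(groupsList, function(v) sum((v - mean(v))^2), 0))
  if (mse0 > 0) return(NULL)
  means <- vapply(groupsList, mean, 0)
  if (max(means) - min(means) == 0) list(F = 0, p = 1) else
    list(F = Inf, p = 0)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Compares a quantitative trait among groups: overall F test
#' ([stats::aov()]), Tukey honest-significant-difference pairwise
#' comparisons ([stats::TukeyHSD()]), and a compact letter display in the
#' group-mean-table convention (letter "a" on the largest mean; levels
#' sharing a letter are pairwise non-significant at `alpha`). Degenerate
#' inputs are handled explicitly: if all observations are identical the
#' result is `F = 0`, `p = 1`, one shared letter; if the residual variance
#' is zero but means differ, `F = Inf`, `p = 0`.
#'
#' @param values numeric response vector.
#' @param groups factor/character vector of group labels (>= 2 groups,
#'   each with n >= 2).
#' @param alpha significance threshold for the letters.
#' @return an [AnovaResult-class] with `method = "tukey"`.
#' @export
anovaOnewayTukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups are required")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  if (anyNA(values)) stop("missing values are not allowed")
  byGroup <- split(values, groups)
  means <- vapply(byGroup, mean, 0)
  ordLv <- names(sort(means, decreasing = TRUE))
  prs <- utils::combn(levels(groups), 2)
  dfRes <- length(values) - nlevels(groups)

  deg <- anovaGuardDegenerate(values, byGroup)
  if (!is.null(deg)) {
    pw <- data.frame(term = "group", level1 = prs[1, ], level2 = prs[2, ],
                     estimate = means[prs[2, ]] - means[prs[1, ]],
                     p = if (is.infinite(deg$F))
                       ifelse(means[prs[1, ]] != means[prs[2, ]], 0, 1) else 1,
                     stringsAsFactors = FALSE)
  } else {
    fit <- stats::aov(values ~ groups)
    at <- stats::anova(fit)
    deg <- list(F = at$`F value`[1], p = at$`Pr(>F)`[1])
    tk <- stats::TukeyHSD(fit)$groups
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pw <- data.frame(term = "group", level1 = cmp[, 2], level2 = cmp[, 1],
                     estimate = tk[, "diff"], p = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  }
  rownames(pw) <- NULL
  sig <- pw[pw$p < alpha, , drop = FALSE]
  lets <- compactLetters(ordLv, sig)
  new("AnovaResult",
      terms = data.frame(term = "group", df = nlevels(groups) - 1,
                         F = deg$F, p = deg$p, stringsAsFactors = FALSE),
      pairwise = pw, letters = list(group = lets),
      means = list(group = means), method = "tukey", alpha = alpha,
      residualDf = dfRes)
}

lsdPairwise <- function(term, means, ns, mse, dfRes) {
  means <- stats::setNames(as.numeric(means), names(means))
  ns <- stats::setNames(as.numeric(ns), names(ns))
  lv <- names(means)
  prs <- utils::combn(lv, 2)
  est <- means[prs[2, ]] - means[prs[1, ]]
  se <- sqrt(mse * (1 / ns[prs[1, ]] + 1 / ns[prs[2, ]]))
  p <- if (mse == 0) ifelse(est != 0, 0, 1) else
    2 * stats::pt(-abs(est / se), df = dfRes)
  data.frame(term = term, level1 = prs[1, ], level2 = prs[2, ],
             estimate = unname(est), p = unname(as.numeric(p)),
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA with LSD post-hoc tests
#'
#' Main-effect F tests for two crossed factors (e.g. diet group and
#' scanning plane) fitted without interaction by default — the usual model
#' when only main effects are reported — followed by least-significant-
#' difference pairwise comparisons within each factor: plain t tests using
#' the ANOVA residual mean square, unadjusted. A factor with a single level
#' is dropped with a message (the model then degenerates to a one-way
#' ANOVA). Empty factor combinations are an error.
#'
#' @param values numeric response vector.
#' @param group,plane the two factors (character or factor).
#' @param alpha significance threshold for the letters.
#' @param interaction include the interaction term (default `FALSE`).
#' @return an [AnovaResult-class] with `method = "lsd"`, one letter display
#'   per retained factor.
#' @export
anovaTwowayLsd <- function(values, group, plane, alpha = 0.05,
                           interaction = FALSE) {
  group <- factor(group); plane <- factor(plane)
  if (anyNA(values)) stop("missing values are not allowed")
  cellCounts <- table(group, plane)
  if (nlevels(group) >= 2 && nlevels(plane) >= 2 && any(cellCounts == 0)) {
    bad <- which(cellCounts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: group '%s' x plane '%s' has no observations",
                 levels(group)[bad[1]], levels(plane)[bad[2]]))
  }
  factors <- list(group = group, plane = plane)
  keep <- vapply(factors, nlevels, 1L) >= 2
  if (!any(keep)) stop("at least one factor needs 2 or more levels")
  if (!all(keep))
    message("factor '", names(factors)[!keep],
            "' has a single level and is dropped")
  factors <- factors[keep]
  if (interaction && length(factors) == 2 && any(cellCounts == 1)) {
    message("interaction dropped: at least one cell has n = 1")
    interaction <- FALSE
  }
  dat <- data.frame(y = values, factors)
  form <- if (length(factors) == 2) {
    if (interaction) y ~ group * plane else y ~ group + plane
  } else {
    stats::reformulate(names(factors), response = "y")
  }
  totSS <- sum((values - mean(values))^2)
  degenerate <- totSS <= 1e-12 * length(values) * max(1, mean(values)^2)
  if (degenerate) {
    ## all observations (numerically) identical: F = 0, p = 1 throughout
    termNames <- names(factors)
    if (interaction && length(factors) == 2)
      termNames <- c(termNames, "group:plane")
    dfs <- vapply(factors, function(f) nlevels(f) - 1L, 1L)
    if (interaction && length(factors) == 2) dfs <- c(dfs, prod(dfs[1:2]))
    dfRes <- length(values) - 1L - sum(dfs)
    mse <- 0
    terms <- data.frame(term = termNames, df = unname(dfs),
                        F = 0, p = 1, stringsAsFactors = FALSE)
  } else {
    fit <- stats::aov(form, data = dat)
    at <- stats::anova(fit)
    nterms <- nrow(at) - 1L
    dfRes <- at$Df[nrow(at)]
    mse <- at$`Mean Sq`[nrow(at)]
    terms <- data.frame(term = trimws(rownames(at)[seq_len(nterms)]),
                        df = at$Df[seq_len(nterms)],
                        F = at$`F value`[seq_len(nterms)],
                        p = at$`Pr(>F)`[seq_len(nterms)],
                        stringsAsFactors = FALSE)
    if (mse <= 1e-12 * totSS / length(values)) {
      ## zero residual variance but structured means: perfect separation
      mse <- 0
      for (k in seq_len(nrow(terms))) {
        ssq <- at$`Sum Sq`[k]
        terms$F[k] <- if (ssq <= 1e-12 * totSS) 0 else Inf
        terms$p[k] <- if (ssq <= 1e-12 * totSS) 1 else 0
      }
    }
  }
  pwList <- list(); letsList <- list(); meansList <- list()
  for (f in names(factors)) {
    means <- tapply(values, factors[[f]], mean)
    ns <- table(factors[[f]])
    pw <- lsdPairwise(f, means, ns, mse, dfRes)
    sig <- pw[pw$p < alpha, , drop = FALSE]
    ordLv <- names(sort(means, decreasing = TRUE))
    pwList[[f]] <- pw
    letsList[[f]] <- compactLetters(ordLv, sig)
    meansList[[f]] <- means
  }
  new("AnovaResult", terms = terms, pairwise = do.call(rbind, pwList),
      letters = letsList, means = meansList, method = "lsd", alpha = alpha,
      residualDf = dfRes)
}
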