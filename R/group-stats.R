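#' Build the per-instance cohort table for statistics
#'
#' Joins per-instance metadata (subject, group, side, age, gender) with
#' the per-mode shape parameters. Metadata rows are matched to shape
#' parameter rows by `instance_id`.
#'
#' @param metadata data.frame with columns subject_id, instance_id, group
#'   (one of "CAI", "CAI_CONTRA", "HEALTHY"), side ("L"/"R"), age,
#'   gender ("M"/"F").
#' @param params a [ShapeParameters-class]; rows must be named by
#'   instance id.
#' @return a data.frame with the metadata plus columns `b<k>` (raw) and
#'   `bsd<k>` (SD units) per retained mode.
#' @export
makeCohortTable <- function(metadata, params) {
  need <- c("subject_id", "instance_id", "group", "side", "age", "gender")
  stopIf(!all(need %in% names(metadata)),
    paste("metadata must contain columns:", paste(need, collapse = ", "))
  )
  stopIf(!all(metadata$group %in% c("CAI", "CAI_CONTRA", "HEALTHY")),
    "group labels must be CAI, CAI_CONTRA or HEALTHY"
  )
  dup <- duplicated(metadata[, c("subject_id", "side")])
  stopIf(any(dup), "a subject may contribute at most one instance per side")
  b <- params@b
  nb <- params@normalizedB
  idx <- match(metadata$instance_id, rownames(b))
  stopIf(anyNA(idx), "every metadata instance_id must have shape parameters")
  out <- metadata
  for (k in seq_len(ncol(b))) {
    out[[paste0("b", k)]] <- b[idx, k]
    out[[paste0("bsd", k)]] <- nb[idx, k]
  }
  out
}

nModesInTable <- function(table) {
  sum(grepl("^bsd[0-9]+$", names(table)))
}

# memoised Monte-Carlo null of the Lilliefors statistic, per sample size
.lillieforsCache <- new.env(parent = emptyenv())

lillieforsStat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

lillieforsNull <- function(n, nSim = 10000L, seed = 20260101) {
  key <- sprintf("n%d_s%d", n, nSim)
  got <- .lillieforsCache[[key]]
  if (!is.null(got)) return(got)
  d <- withSeed(seed, {
    X <- matrix(rnorm(n * nSim), nrow = n)
    X <- sweep(X, 2L, colMeans(X))
    X <- sweep(X, 2L, sqrt(colSums(X^2) / (n - 1)), "/")
    Z <- apply(X, 2L, sort)
    P <- pnorm(Z)
    i <- seq_len(n)
    pmax(
      apply(i / n - P, 2L, max),
      apply(P - (i - 1) / n, 2L, max)
    )
  })
  .lillieforsCache[[key]] <- d
  d
}

#' Kolmogorov-Smirnov normality screen with estimated parameters
#'
#' One-sample KS test of each mode's b values against a normal with the
#' sample mean and SD. Because the parameters are estimated, the naive KS
#' null is anti-conservative; the p-value is therefore taken from a
#' Monte-Carlo Lilliefors null (10,000 simulated samples per sample size,
#' memoised).
#'
#' @param b numeric vector (>= 5 values) or matrix/data.frame of per-mode
#'   columns.
#' @param nSim Monte-Carlo null size.
#' @return p-value (or named vector of p-values, one per column).
#'   Zero-variance input gives p = 0 with a degenerate-distribution
#'   warning.
#' @export
ksNormality <- function(b, nSim = 10000L) {
  if (is.matrix(b) || is.data.frame(b)) {
    return(vapply(as.data.frame(b), ksNormality, numeric(1), nSim = nSim))
  }
  b <- as.numeric(b)
  stopIf(length(b) < 5L, "need at least 5 values per mode")
  if (sd(b) < 1e-12 * (abs(mean(b)) + 1)) {
    warning("degenerate (constant) distribution; reporting p = 0", call. = FALSE)
    return(0)
  }
  d <- lillieforsStat(b)
  null <- lillieforsNull(length(b), nSim = as.integer(nSim))
  (1 + sum(null >= d)) / (length(null) + 1)
}

pairKey <- function(a, b) paste(sort(c(a, b)), collapse = " vs ")

.groupPairs <- list(
  c("CAI", "CAI_CONTRA"), c("CAI", "HEALTHY"), c("CAI_CONTRA", "HEALTHY")
)

#' One-way ANOVA with Bonferroni post-hoc pairwise tests, per mode
#'
#' For each retained mode, the SD-normalised shape parameters are
#' compared across the three groups with a fixed-effects one-way ANOVA
#' F-test; the three pairwise comparisons use two-sample t-tests with the
#' variance pooled across all groups (classic Bonferroni post-hoc after
#' ANOVA), with raw p-values multiplied by 3 and capped at 1. A Welch
#' pairing (no pooling) is available via `pool = FALSE`.
#'
#' @param table a cohort table from [makeCohortTable()].
#' @param pool pool the within-group variance across all groups
#'   (default TRUE).
#' @return data.frame with one row per mode x comparison (comparison
#'   "omnibus" plus the three pairs), columns p_raw and p_adjusted.
#'   A group with fewer than 3 instances flags the mode unavailable
#'   (NA p-values).
#' @export
anovaPerMode <- function(table, pool = TRUE) {
  nModes <- nModesInTable(table)
  stopIf(nModes < 1L, "table has no shape-parameter columns")
  g <- factor(table$group)
  stopIf(nlevels(g) < 2L, "need at least 2 groups")
  small <- any(tabulate(g) < 3L)
  out <- list()
  for (k in seq_len(nModes)) {
    x <- table[[paste0("bsd", k)]]
    if (small) {
      rows <- data.frame(
        mode = k,
        comparison = c("omnibus", vapply(.groupPairs, function(p) pairKey(p[1], p[2]), "")),
        p_raw = NA_real_, p_adjusted = NA_real_, available = FALSE
      )
      out[[k]] <- rows
      next
    }
    omni <- oneway.test(x ~ g, var.equal = TRUE)$p.value
    pw <- pairwise.t.test(x, g, p.adjust.method = "none", pool.sd = pool)$p.value
    rows <- data.frame(
      mode = k, comparison = "omnibus",
      p_raw = omni, p_adjusted = omni, available = TRUE
    )
    for (pr in .groupPairs) {
      if (!all(pr %in% levels(g))) next
      p <- pw[pr[2], pr[1]]
      if (is.na(p)) p <- pw[pr[1], pr[2]]
      rows <- rbind(rows, data.frame(
        mode = k, comparison = pairKey(pr[1], pr[2]),
        p_raw = p, p_adjusted = min(1, 3 * p), available = TRUE
      ))
    }
    out[[k]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age- and gender-adjusted group effect, per mode
#'
#' Fits the linear model b ~ group + age + gender per mode and tests the
#' group effect by the extra-sum-of-squares F-test against the
#' covariate-only model. Constant covariates (for instance a single
#' gender) are dropped with a warning.
#'
#' @param table a cohort table from [makeCohortTable()] with complete age
#'   and gender.
#' @return data.frame with columns mode and p (ANCOVA group-effect
#'   p-value).
#' @export
ancovaPerMode <- function(table) {
  nModes <- nModesInTable(table)
  stopIf(nModes < 1L, "table has no shape-parameter columns")
  stopIf(!all(complete.cases(table[, c("age", "gender")])),
    "age and gender must be present for every instance"
  )
  covars <- character(0)
  if (length(unique(table$age)) > 1L) {
    covars <- c(covars, "age")
  } else {
    warning("age is constant; dropping it from the ANCOVA", call. = FALSE)
  }
  if (length(unique(table$gender)) > 1L) {
    covars <- c(covars, "gender")
  } else {
    warning("gender has a single level; dropping it from the ANCOVA", call. = FALSE)
  }
  rhs0 <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  out <- lapply(seq_len(nModes), function(k) {
    df <- data.frame(
      y = table[[paste0("bsd", k)]], group = factor(table$group),
      age = table$age, gender = factor(table$gender)
    )
    f0 <- lm(stats::as.formula(paste("y ~", rhs0)), data = df)
    f1 <- lm(stats::as.formula(paste("y ~ group +", rhs0)), data = df)
    data.frame(mode = k, p = anova(f0, f1)[2, "Pr(>F)"])
  })
  do.call(rbind, out)
}

#' Mode-wise three-group comparison of bone shape parameters
#'
#' Orchestrates, for every retained mode: the Lilliefors-style KS
#' normality screen, the one-way ANOVA omnibus test with
#' Bonferroni-adjusted pairwise post-hoc t-tests, and the age- and
#' gender-adjusted ANCOVA group test. A mode is flagged significant for a
#' group pair only when its Bonferroni-adjusted pairwise p-value is below
#' `alpha`. The result also records whether covariate adjustment changed
#' any omnibus significance flag.
#'
#' The three groups share subjects (an ipsilateral and a contralateral
#' ankle per CAI patient, and both ankles of bilateral healthy controls),
#' so the independent-groups treatment is an approximation; a warning
#' notes this, and `healthyPolicy = "one-per-subject"` restricts healthy
#' controls to one ankle each.
#'
#' @param table a cohort table from [makeCohortTable()].
#' @param alpha significance level in (0, 1); default 0.05. No
#'   multiplicity correction is applied across modes.
#' @param healthyPolicy "both" (default) or "one-per-subject".
#' @param warnNonIndependence emit the non-independence warning
#'   (default TRUE).
#' @return a [ComparisonResult-class].
#' @export
runComparison <- function(table, alpha = 0.05,
                          healthyPolicy = c("both", "one-per-subject"),
                          warnNonIndependence = TRUE) {
  healthyPolicy <- match.arg(healthyPolicy)
  stopIf(alpha <= 0 || alpha > 1, "alpha must be in (0, 1]")
  if (healthyPolicy == "one-per-subject") {
    healthy <- table$group == "HEALTHY"
    keep <- !healthy | !duplicated(table$subject_id)
    # keep the first (by convention, left) ankle of each healthy subject
    ord <- order(table$subject_id, table$side)
    tableH <- table[ord, ][keep[ord], ]
    table <- tableH[order(match(tableH$instance_id, table$instance_id)), ]
  }
  multi <- any(duplicated(table$subject_id))
  if (multi && warnNonIndependence) {
    warning(paste(
      "groups share subjects (ipsilateral/contralateral ankles);",
      "pairwise tests treat instances as independent"
    ), call. = FALSE)
  }
  nModes <- nModesInTable(table)
  ks <- vapply(seq_len(nModes), function(k) {
    ksNormality(table[[paste0("bsd", k)]])
  }, numeric(1))
  av <- anovaPerMode(table)
  ac <- ancovaPerMode(table)

  # at the boundary alpha = 1 every test is significant by convention
  # (adjusted p-values are capped at exactly 1)
  sigAt <- function(p) !is.na(p) & (p < alpha | alpha >= 1)
  pw <- av[av$comparison != "omnibus", ]
  pw$significant <- sigAt(pw$p_adjusted)
  omni <- av[av$comparison == "omnibus", ]

  results <- rbind(
    data.frame(
      mode = seq_len(nModes), test = "ks_normality", comparison = "all",
      p_raw = ks, p_adjusted = ks, significant = sigAt(ks)
    ),
    data.frame(
      mode = omni$mode, test = "anova", comparison = "omnibus",
      p_raw = omni$p_raw, p_adjusted = omni$p_adjusted,
      significant = sigAt(omni$p_adjusted)
    ),
    data.frame(
      mode = pw$mode, test = "pairwise_bonferroni", comparison = pw$comparison,
      p_raw = pw$p_raw, p_adjusted = pw$p_adjusted, significant = pw$significant
    ),
    data.frame(
      mode = ac$mode, test = "ancova", comparison = "omnibus",
      p_raw = ac$p, p_adjusted = ac$p,
      significant = sigAt(ac$p)
    )
  )
  rownames(results) <- NULL

  flagged <- vapply(seq_len(nModes), function(k) {
    sig <- pw[pw$mode == k & pw$significant, "comparison"]
    paste(sig, collapse = "; ")
  }, character(1))
  modeSummary <- data.frame(
    mode = seq_len(nModes), ks_p = ks,
    anova_p = omni$p_raw[match(seq_len(nModes), omni$mode)],
    ancova_p = ac$p[match(seq_len(nModes), ac$mode)],
    flagged = flagged
  )
  anovaSig <- !is.na(modeSummary$anova_p) & modeSummary$anova_p < alpha
  ancovaSig <- !is.na(modeSummary$ancova_p) & modeSummary$ancova_p < alpha
  new("ComparisonResult",
    results = results, modeSummary = modeSummary, alpha = alpha,
    ancovaChanged = any(anovaSig != ancovaSig)
  )
}

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(
    "ComparisonResult: %d modes at alpha = %g\n",
    nrow(object@modeSummary), object@alpha
  ))
  for (k in seq_len(nrow(object@modeSummary))) {
    r <- object@modeSummary[k, ]
    fl <- if (nzchar(r$flagged)) r$flagged else "-"
    cat(sprintf(
      "  mode %d: KS p = %.3f, ANOVA p = %.4f, ANCOVA p = %.4f, significant: %s\n",
      r$mode, r$ks_p, r$anova_p, r$ancova_p, fl
    ))
  }
  cat(sprintf(
    "  covariate adjustment changed omnibus flags: %s\n",
    if (object@ancovaChanged) "yes" else "no"
  ))
})

#' Pairwise significance flags of a comparison
#'
#' @param result a [ComparisonResult-class].
#' @return logical matrix modes x comparisons of Bonferroni-adjusted
#'   pairwise significance.
#' @export
pairwiseFlags <- function(result) {
  pw <- result@results[result@results$test == "pairwise_bonferroni", ]
  comps <- vapply(.groupPairs, function(p) pairKey(p[1], p[2]), "")
  nModes <- max(pw$mode)
  out <- matrix(FALSE, nModes, length(comps), dimnames = list(NULL, comps))
  for (i in seq_len(nrow(pw))) {
    out[pw$mode[i], pw$comparison[i]] <- isTRUE(pw$significant[i])
  }
  out
}

#' Write tidy comparison results
#'
#' @param result a [ComparisonResult-class].
#' @param csvPath tidy CSV output (mode, test, comparison, p_raw,
#'   p_adjusted, significant).
#' @param jsonPath optional JSON summary path.
#' @return `csvPath`, invisibly.
#' @export
writeComparison <- function(result, csvPath, jsonPath = NULL) {
  write.csv(result@results, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(
        alpha = result@alpha,
        ancova_changed_flags = result@ancovaChanged,
        modes = result@modeSummary
      ),
      jsonPath,
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(csvPath)
}

#' Box plot of shape parameters by group for one mode
#'
#' The standard presentation of a significant mode: per-group
#' distributions of the SD-normalised shape parameters.
#'
#' @param table a cohort table from [makeCohortTable()].
#' @param mode mode index.
#' @return a ggplot object.
#' @export
plotModeBoxplot <- function(table, mode) {
  col <- paste0("bsd", as.integer(mode))
  stopIf(!col %in% names(table), sprintf("mode %s not present in table", mode))
  df <- data.frame(group = table$group, b = table[[col]])
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = b)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(
      x = NULL, y = sprintf("Mode %d shape parameter (SD units)", as.integer(mode)),
      title = sprintf("Shape mode %d by group", as.integer(mode))
    ) +
    ggplot2::theme_minimal()
}

#' Statistic-level replicates from a fitted b-structure
#'
#' Re-draws per-instance shape parameters from independent normals with
#' the fitted per-mode variances (the null: identical group
#' distributions, optionally with a planted mean offset), reruns the
#' mode-wise statistics for each replicate, and returns the pairwise and
#' per-mode flag frequencies. This separates the statistical calibration
#' of the comparison stage from the geometric stages.
#'
#' @param metadata instance metadata (as in [makeCohortTable()]).
#' @param eigenvalues fitted per-mode variances.
#' @param nReps number of replicates.
#' @param alpha significance level.
#' @param effectSize mean offset in SD units added to the CAI group (and
#'   `contraFraction` of it to CAI_CONTRA) on `effectMode`.
#' @param effectMode mode carrying the offset.
#' @param contraFraction fraction of the effect for contralateral
#'   instances.
#' @param seed integer seed.
#' @param withAncova also run the ANCOVA per replicate (default TRUE).
#' @return list with `pairRate` (per mode x comparison flag frequency),
#'   `modeAnyRate` (frequency with which a mode is flagged in any
#'   comparison), `agreeRate` (ANOVA/ANCOVA omnibus flag agreement, NA if
#'   `withAncova = FALSE`) and the replicate count.
#' @export
simulateStatReplicates <- function(metadata, eigenvalues, nReps = 1000L,
                                   alpha = 0.05, effectSize = 0,
                                   effectMode = 1L, contraFraction = 1,
                                   seed = 1L, withAncova = TRUE) {
  nModes <- length(eigenvalues)
  nInst <- nrow(metadata)
  g <- factor(metadata$group)
  comps <- vapply(.groupPairs, function(p) pairKey(p[1], p[2]), "")
  pairHits <- matrix(0, nModes, length(comps), dimnames = list(NULL, comps))
  anyHits <- numeric(nModes)
  agree <- 0L
  agreeN <- 0L
  offset <- numeric(nInst)
  offset[metadata$group == "CAI"] <- effectSize
  offset[metadata$group == "CAI_CONTRA"] <- effectSize * contraFraction
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      b <- matrix(rnorm(nInst * nModes), nInst, nModes)
      b <- sweep(b, 2L, sqrt(eigenvalues), "*")
      b[, effectMode] <- b[, effectMode] + offset * sqrt(eigenvalues[effectMode])
      tab <- metadata
      for (k in seq_len(nModes)) {
        tab[[paste0("b", k)]] <- b[, k]
        tab[[paste0("bsd", k)]] <- b[, k] / sqrt(eigenvalues[k])
      }
      av <- anovaPerMode(tab)
      pw <- av[av$comparison != "omnibus", ]
      for (i in seq_len(nrow(pw))) {
        hit <- !is.na(pw$p_adjusted[i]) && pw$p_adjusted[i] < alpha
        if (hit) pairHits[pw$mode[i], pw$comparison[i]] <-
            pairHits[pw$mode[i], pw$comparison[i]] + 1
      }
      for (k in seq_len(nModes)) {
        sub <- pw[pw$mode == k, ]
        if (any(!is.na(sub$p_adjusted) & sub$p_adjusted < alpha)) {
          anyHits[k] <- anyHits[k] + 1
        }
      }
      if (withAncova) {
        ac <- suppressWarnings(ancovaPerMode(tab))
        omni <- av[av$comparison == "omnibus", ]
        aFlag <- !is.na(omni$p_raw) & omni$p_raw < alpha
        cFlag <- !is.na(ac$p) & ac$p < alpha
        agree <- agree + sum(aFlag == cFlag)
        agreeN <- agreeN + length(aFlag)
      }
    }
  })
  list(
    pairRate = pairHits / nReps,
    modeAnyRate = anyHits / nReps,
    agreeRate = if (withAncova) agree / agreeN else NA_real_,
    nReps = nReps
  )
}
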