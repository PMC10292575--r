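# Group-level inference: linear mixed models over timepoints (Satterthwaite
# df), paired/two-sample t tests with Benjamini-Hochberg correction, and the
# wiring-cost vs resilience rank correlation.

test_result <- function(name, statistic, df, p_raw, method,
                        family = NA_character_, note = NA_character_) {
  data.frame(name = name, statistic = statistic,
             df = if (length(df) == 2L) sprintf("%.4g, %.4g", df[1L], df[2L])
                  else as.character(df),
             p_raw = p_raw, p_adjusted = NA_real_, family = family,
             method = method, note = note, stringsAsFactors = FALSE)
}

validate_cohort_table <- function(table) {
  need <- c("subject_id", "group", "timepoint", "outcome")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$outcome)))
    stop("non-finite outcomes in cohort table")
  invisible(table)
}

#' Fit the longitudinal mixed model for a timepoint effect
#'
#' Restricted-maximum-likelihood linear mixed model on patient rows with the
#' outcome (an AUC value) as dependent variable, timepoint plus any
#' non-constant lesion covariates (volume, side) as fixed effects -- with an
#' optional timepoint x attack-type interaction -- and a random intercept per
#' subject. The omnibus timepoint effect is the Type-III F test with
#' Satterthwaite degrees of freedom; when that fit fails, a likelihood-ratio
#' test of the timepoint factor is used and flagged in the \code{method}
#' column.
#'
#' @param table long-format cohort table with columns \code{subject_id},
#'   \code{group}, \code{timepoint}, \code{outcome} and optionally
#'   \code{lesion_volume_cm3}, \code{lesion_side}, \code{attack_type}.
#' @param include_attack_interaction add \code{attack_type} and its
#'   interaction with timepoint (requires an \code{attack_type} column).
#' @return one-row data.frame: statistic (F or chi-square), df, raw p,
#'   method used, and notes (e.g. dropped constant covariates or singular
#'   fits).
#' @export
fit_longitudinal_model <- function(table, include_attack_interaction = FALSE) {
  validate_cohort_table(table)
  pat <- table[table$group == "patient", , drop = FALSE]
  if (length(unique(pat$timepoint)) < 2L)
    stop("need at least 2 patient timepoints")
  if (length(unique(pat$subject_id)) < 3L)
    stop("need at least 3 patients")
  notes <- character(0)

  if (stats::sd(pat$outcome) < 1e-12) {
    # degenerate: a constant outcome carries no timepoint effect and no
    # between-subject variance; report p = 1 without fitting
    return(test_result("timepoint", 0, NA_real_, 1, "degenerate-constant",
                       note = "constant outcome; between-subject variance 0"))
  }

  pat$timepoint <- factor(pat$timepoint)
  pat$subject_id <- factor(pat$subject_id)
  terms <- "timepoint"
  if (include_attack_interaction) {
    if (is.null(pat$attack_type))
      stop("include_attack_interaction needs an attack_type column")
    pat$attack_type <- factor(pat$attack_type)
    terms <- c(terms, "attack_type", "timepoint:attack_type")
  }
  for (cov in c("lesion_volume_cm3", "lesion_side")) {
    if (!is.null(pat[[cov]]) && length(unique(pat[[cov]])) > 1L) {
      terms <- c(terms, cov)
    } else if (!is.null(pat[[cov]])) {
      notes <- c(notes, paste0(cov, " constant, dropped"))
    }
  }
  fml <- stats::as.formula(paste("outcome ~", paste(terms, collapse = " + "),
                                 "+ (1 | subject_id)"))
  fit_warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    fit_warnings <<- unique(c(fit_warnings, conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  fit <- tryCatch(
    collect(suppressMessages(lmerTest::lmer(fml, data = pat, REML = TRUE))),
    error = function(e) e)
  if (!inherits(fit, "error")) {
    if (lme4::isSingular(fit, tol = 1e-5))
      notes <- c(notes, "singular random-effect fit (variance near 0)")
    if (length(fit_warnings))
      notes <- c(notes, paste("fit warnings:",
                              paste(trimws(fit_warnings), collapse = "; ")))
    an <- tryCatch(collect(stats::anova(fit, type = 3,
                                        ddf = "Satterthwaite")),
                   error = function(e) e)
    if (!inherits(an, "error") && "timepoint" %in% rownames(an)) {
      row <- an["timepoint", ]
      return(test_result("timepoint", row[["F value"]],
                         c(row[["NumDF"]], row[["DenDF"]]),
                         row[["Pr(>F)"]], "lmm-satterthwaite",
                         note = paste(notes, collapse = "; ")))
    }
  }
  # fallback: likelihood-ratio test of the timepoint factor (ML fits)
  terms0 <- setdiff(terms, c("timepoint", "timepoint:attack_type"))
  fml0 <- stats::as.formula(paste(
    "outcome ~", if (length(terms0)) paste(terms0, collapse = " + ") else "1",
    "+ (1 | subject_id)"))
  f1 <- suppressMessages(lme4::lmer(fml, data = pat, REML = FALSE))
  f0 <- suppressMessages(lme4::lmer(fml0, data = pat, REML = FALSE))
  lrt <- stats::anova(f0, f1)
  test_result("timepoint", lrt$Chisq[2L], lrt$Df[2L],
              lrt[["Pr(>Chisq)"]][2L], "lmm-lrt-fallback",
              note = paste(c(notes, "Satterthwaite unavailable"),
                           collapse = "; "))
}

contrast_values <- function(table, label) {
  if (label %in% c("control", "controls", "single")) {
    rows <- table$group == "control"
  } else {
    rows <- table$group == "patient" & table$timepoint == label
  }
  v <- table[rows, c("subject_id", "outcome")]
  v[order(v$subject_id), ]
}

#' Pairwise timepoint and group comparisons
#'
#' Paired t tests for within-patient timepoint contrasts and Welch
#' two-sample t tests for patient-vs-control contrasts, two-sided, with
#' Benjamini-Hochberg adjustment applied within each family.
#'
#' @param table long-format cohort table (see
#'   \code{\link{fit_longitudinal_model}}).
#' @param contrasts list of contrasts, each a list with elements \code{a} and
#'   \code{b} (a timepoint label or \code{"control"}) and \code{paired}
#'   (logical). Default: the three paired TP contrasts plus each TP against
#'   controls.
#' @param family label stored with every test; BH adjustment runs within it.
#' @return data.frame of test results with \code{p_adjusted} filled in.
#' @export
pairwise_comparisons <- function(table, contrasts = NULL,
                                 family = "comparisons") {
  validate_cohort_table(table)
  if (is.null(contrasts)) {
    contrasts <- list(
      list(a = "TP1", b = "TP2", paired = TRUE),
      list(a = "TP2", b = "TP3", paired = TRUE),
      list(a = "TP1", b = "TP3", paired = TRUE))
    if (any(table$group == "control"))
      contrasts <- c(contrasts, lapply(c("TP1", "TP2", "TP3"), function(tp)
        list(a = tp, b = "control", paired = FALSE)))
  }
  res <- lapply(contrasts, function(ct) {
    va <- contrast_values(table, ct$a)
    vb <- contrast_values(table, ct$b)
    nm <- sprintf("%s vs %s%s", ct$a, ct$b,
                  if (isTRUE(ct$paired)) " (paired)" else "")
    if (isTRUE(ct$paired)) {
      common <- intersect(va$subject_id, vb$subject_id)
      if (length(common) < 3L) stop(nm, ": fewer than 3 matched subjects")
      d <- va$outcome[match(common, va$subject_id)] -
           vb$outcome[match(common, vb$subject_id)]
      if (stats::sd(d) < 1e-12) {
        p <- if (max(abs(d)) < 1e-12) 1 else NA_real_
        return(test_result(nm, 0, length(d) - 1L, p, "paired-t",
                           family = family,
                           note = "zero variance of paired differences"))
      }
      tt <- stats::t.test(d)
      test_result(nm, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, "paired-t", family = family)
    } else {
      if (nrow(va) < 3L || nrow(vb) < 3L)
        stop(nm, ": fewer than 3 observations per side")
      tt <- stats::t.test(va$outcome, vb$outcome, var.equal = FALSE)
      test_result(nm, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, "welch-t", family = family)
    }
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- bh_adjust(out$p_raw[ok])
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values within one family:
#' \code{adj_(i) = min_{j >= i} (m p_(j) / j)}, capped at 1, mapped back to
#' the input order.
#'
#' @param p_values numeric vector of raw p values in \[0, 1\].
#' @return adjusted p values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Correlation between resilience change and wiring-cost change
#'
#' Spearman rank correlation between per-subject TP3 - TP2 changes in
#' post-attack AUC of global efficiency and the matching changes in AUC of
#' mean degree. The p value is exact for n < 10 (no ties), otherwise the
#' t approximation.
#'
#' @param delta_resilience per-subject change in post-attack AUC(E_glob).
#' @param delta_cost per-subject change in AUC(mean degree), same order.
#' @return list with \code{rho}, \code{p}, \code{n} and \code{method}.
#' @export
cost_resilience_correlation <- function(delta_resilience, delta_cost) {
  stopifnot(length(delta_resilience) == length(delta_cost))
  n <- length(delta_resilience)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(delta_resilience) < 1e-15 || stats::sd(delta_cost) < 1e-15) {
    warning("constant input vector; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  exact <- n < 10L
  ct <- suppressWarnings(
    stats::cor.test(delta_resilience, delta_cost, method = "spearman",
                    exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (exact) "spearman-exact" else "spearman-t")
}

#' Write a tidy results table and a short human-readable report
#'
#' @param results data.frame of test results (rows from
#'   \code{\link{pairwise_comparisons}} / \code{\link{fit_longitudinal_model}}).
#' @param path CSV path; the report goes to \code{<path>.txt}.
#' @export
write_test_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  lines <- sprintf("%-28s %-14s stat=%8.4g  p=%.4g  p_adj=%s  [%s]",
                   results$name, paste0("(", results$family, ")"),
                   results$statistic, results$p_raw,
                   ifelse(is.na(results$p_adjusted), "-",
                          sprintf("%.4g", results$p_adjusted)),
                   results$method)
  writeLines(lines, paste0(path, ".txt"))
  invisible(path)
}
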