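# Statistical design: linear mixed models fitted by maximum likelihood,
# per-term likelihood-ratio chi-squares (drop-one), per-cell mean +/- SD
# summaries, and the Spearman/Bonferroni correlation screen against the
# number of fragments per instruction.

#' Specify a mixed-model analysis
#'
#' @param response metric column name (e.g. `"mean_dilation"`).
#' @param fixed character vector of fixed-factor column names, e.g.
#'   `c("fragment", "role")`; each must have at least two levels in the data.
#' @param interaction include the two-way interaction of the first two fixed
#'   factors.
#' @param random character vector of random-intercept grouping columns
#'   (default: interaction and instructed object).
#' @return a `model_spec`.
#' @export
model_spec <- function(response, fixed, interaction = length(fixed) >= 2,
                       random = c("interaction_id", "referent_id")) {
  stopifnot(length(fixed) >= 1, is.character(response))
  structure(list(response = response, fixed = fixed,
                 interaction = interaction && length(fixed) >= 2,
                 random = random),
            class = "model_spec")
}

re_terms <- function(random) {
  if (length(random) == 0) return("")
  paste(sprintf("(1 | %s)", random), collapse = " + ")
}

build_formula <- function(response, fixed_part, random) {
  rhs <- if (length(random) > 0) {
    paste(fixed_part, re_terms(random), sep = " + ")
  } else {
    fixed_part
  }
  stats::as.formula(paste(response, "~", rhs))
}

# Fit by ML; on a singular random-effects fit, drop the smallest-variance
# grouping term and refit (logged warning), down to a single term.
fit_ml <- function(response, fixed_part, data, random) {
  if (length(random) == 0) {
    return(list(fit = stats::lm(build_formula(response, fixed_part, NULL),
                                data = data),
                random = character()))
  }
  repeat {
    fit <- lme4::lmer(build_formula(response, fixed_part, random),
                      data = data, REML = FALSE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
    if (!lme4::isSingular(fit, tol = 1e-5) || length(random) == 1) {
      return(list(fit = fit, random = random))
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[vc$grp != "Residual", ]
    drop <- vc$grp[which.min(vc$vcov)]
    warning("singular random-effects fit; dropping random intercept for ",
            drop, call. = FALSE)
    random <- setdiff(random, drop)
  }
}

lrt <- function(fit_full, fit_reduced) {
  ll1 <- stats::logLik(fit_full)
  ll0 <- stats::logLik(fit_reduced)
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  df <- attr(ll1, "df") - attr(ll0, "df")
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Fit a mixed model and test each term by likelihood ratio
#'
#' All models are fitted by maximum likelihood (not REML) so that
#' log-likelihoods are comparable across fixed-effects structures. Terms are
#' tested drop-one: each main effect is tested within the additive model
#' (the model without the interaction), and the interaction is tested
#' against the additive model. Each chi-square is twice the log-likelihood
#' difference of the nested pair; degrees of freedom are the parameters
#' added by the term and are reported explicitly.
#'
#' Rows with an undefined (`NA`) response are dropped listwise. A singular
#' random-effects fit falls back to a reduced random structure with a
#' warning; the reduced structure is used for every model in the comparison
#' so the tests stay nested.
#'
#' @param data metric data.frame.
#' @param spec a [model_spec()].
#' @return a `stats_result`: list with `terms` (term, chisq, df, p),
#'   `cells` (per-cell mean/SD/n), `model` descriptor, `n_rows`,
#'   `random_used`.
#' @export
fit_and_test <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  keep <- stats::complete.cases(data[, c(spec$response, spec$fixed,
                                         spec$random), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  for (f in spec$fixed) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      stop("fixed factor ", f, " has fewer than 2 levels after listwise drop")
    }
  }
  random <- spec$random[vapply(spec$random, function(g)
    length(unique(data[[g]])) > 1, logical(1))]

  if (stats::var(data[[spec$response]]) == 0) {
    # degenerate constant response: every nested ML fit is identical
    dfs <- vapply(spec$fixed, function(f) nlevels(data[[f]]) - 1L, integer(1))
    terms <- data.frame(term = spec$fixed, chisq = 0, df = dfs, p = 1,
                        stringsAsFactors = FALSE)
    if (spec$interaction) {
      terms <- rbind(terms, data.frame(
        term = paste(spec$fixed[1], spec$fixed[2], sep = ":"),
        chisq = 0, df = dfs[1] * dfs[2], p = 1))
    }
    return(structure(list(response = spec$response, terms = terms,
                          cells = summarize_cells(data, spec$response,
                                                  spec$fixed),
                          model = sprintf("%s ~ constant response", spec$response),
                          n_rows = nrow(data), random_used = random),
                     class = "stats_result"))
  }

  additive_rhs <- paste(spec$fixed, collapse = " + ")
  # settle the random structure once, on the richest fixed structure
  rich_rhs <- if (spec$interaction) {
    paste0(spec$fixed[1], " * ", spec$fixed[2],
           if (length(spec$fixed) > 2)
             paste(" +", paste(spec$fixed[-(1:2)], collapse = " + ")) else "")
  } else additive_rhs
  rich <- fit_ml(spec$response, rich_rhs, data, random)
  random <- rich$random

  fits <- list()
  fit_with <- function(rhs) {
    if (is.null(fits[[rhs]])) {
      fits[[rhs]] <<- fit_ml(spec$response, rhs, data, random)$fit
    }
    fits[[rhs]]
  }
  terms <- list()
  add_fit <- fit_with(additive_rhs)
  for (f in spec$fixed) {
    reduced_rhs <- paste(setdiff(spec$fixed, f), collapse = " + ")
    if (reduced_rhs == "") reduced_rhs <- "1"
    res <- lrt(add_fit, fit_with(reduced_rhs))
    terms[[f]] <- data.frame(term = f, chisq = res$chisq, df = res$df,
                             p = res$p, stringsAsFactors = FALSE)
  }
  if (spec$interaction) {
    res <- lrt(fit_with(rich_rhs), add_fit)
    terms[["interaction"]] <- data.frame(
      term = paste(spec$fixed[1], spec$fixed[2], sep = ":"),
      chisq = res$chisq, df = res$df, p = res$p, stringsAsFactors = FALSE)
  }
  structure(list(response = spec$response,
                 terms = do.call(rbind, c(terms, list(make.row.names = FALSE))),
                 cells = summarize_cells(data, spec$response, spec$fixed),
                 model = sprintf("%s ~ %s + %s (ML)", spec$response, rich_rhs,
                                 re_terms(random)),
                 n_rows = nrow(data),
                 random_used = random),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  stars <- function(p) ifelse(p <= 0.001, "***",
                              ifelse(p <= 0.01, "**",
                                     ifelse(p <= 0.05, "*", "")))
  cat("<stats_result>", x$model, sprintf("[n = %d]", x$n_rows), "\n")
  tt <- x$terms
  for (i in seq_len(nrow(tt))) {
    cat(sprintf("  %-22s chisq(%d) = %8.2f  p = %.4g %s\n", tt$term[i],
                tt$df[i], tt$chisq[i], tt$p[i], stars(tt$p[i])))
  }
  invisible(x)
}

#' Per-cell mean and standard deviation
#'
#' Unweighted mean and sample SD of a response over every combination of
#' factor levels. A one-row cell reports an empty (`NA`) SD; an empty cell
#' reports empty mean and SD, never zero.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param factors character vector of factor column names.
#' @return data.frame with one row per factor-level combination:
#'   `<factors>..., mean, sd, n`.
#' @export
summarize_cells <- function(data, response, factors) {
  data <- as.data.frame(data)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  levs <- lapply(factors, function(f) sort(unique(as.character(data[[f]]))))
  names(levs) <- factors
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  grid$mean <- NA_real_; grid$sd <- NA_real_; grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- rep(TRUE, nrow(data))
    for (f in factors) sel <- sel & as.character(data[[f]]) == grid[[f]][i]
    v <- data[[response]][sel]
    grid$n[i] <- length(v)
    if (length(v) >= 1) grid$mean[i] <- mean(v)
    if (length(v) >= 2) grid$sd[i] <- stats::sd(v)
  }
  grid
}

#' Spearman correlation screen against fragment counts
#'
#' For each measure, Spearman's rho between the per-instruction measure and
#' the instruction's number of fragments. p-values are Bonferroni-adjusted
#' by the number of correlations screened (capped at 1), and a correlation
#' is flagged `reported` only when |rho| exceeds `rho_threshold` and the
#' adjusted p is below `alpha`. Constant measures have no defined rank
#' correlation and are excluded with a note.
#'
#' @param data one row per instruction (or instruction x role).
#' @param measures character vector of measure column names to screen.
#' @param n_fragments_col column holding the instruction's fragment count.
#' @param rho_threshold magnitude reporting rule (default 0.15).
#' @param alpha significance level applied to adjusted p (default 0.05).
#' @param n_comparisons Bonferroni divisor; defaults to the number of
#'   measures screened, and is recorded in the output.
#' @return data.frame: `measure, rho, p, p_adjusted, n, reported, note`,
#'   with the divisor in attribute `"n_comparisons"`.
#' @export
correlation_screen <- function(data, measures, n_fragments_col = "n_fragments",
                               rho_threshold = 0.15, alpha = 0.05,
                               n_comparisons = length(measures)) {
  data <- as.data.frame(data)
  nf <- data[[n_fragments_col]]
  out <- lapply(measures, function(m) {
    x <- data[[m]]
    keep <- !is.na(x) & !is.na(nf)
    row <- data.frame(measure = m, rho = NA_real_, p = NA_real_,
                      p_adjusted = NA_real_, n = sum(keep),
                      reported = FALSE, note = "", stringsAsFactors = FALSE)
    if (sum(keep) < 3) {
      row$note <- "fewer than 3 observations"
      return(row)
    }
    if (stats::sd(x[keep]) == 0 || stats::sd(nf[keep]) == 0) {
      row$note <- "constant; rank correlation undefined"
      return(row)
    }
    ct <- suppressWarnings(stats::cor.test(x[keep], nf[keep],
                                           method = "spearman", exact = FALSE))
    row$rho <- unname(ct$estimate)
    row$p <- ct$p.value
    row$p_adjusted <- min(1, ct$p.value * n_comparisons)
    row$reported <- abs(row$rho) > rho_threshold && row$p_adjusted < alpha
    row
  })
  out <- do.call(rbind, out)
  attr(out, "n_comparisons") <- n_comparisons
  out
}

#' Aggregate metric rows to one row per instruction and role
#'
#' Averages each measure over the fragments of an instruction (per role) and
#' attaches the instruction's fragment count -- the unit of analysis for
#' [correlation_screen()].
#'
#' @param rows metric data.frame from [compute_metrics()].
#' @param tier_units optional `units` table with `n_fragments`; when absent,
#'   the count is the maximum fragment ordinal observed in `rows`.
#' @return data.frame, one row per (interaction, instruction, role).
#' @export
instruction_level_metrics <- function(rows, tier_units = NULL) {
  measures <- c("first_gaze_to_target", "gaze_to_target", "gaze_to_other",
                "gaze_to_person", "joint_attention", "mutual_gaze",
                "mean_dilation", "peak_dilation", "slope", "duration")
  key <- interaction(rows$interaction_id, rows$instruction_id, rows$role,
                     drop = TRUE)
  agg <- lapply(split(rows, key), function(g) {
    out <- data.frame(interaction_id = g$interaction_id[1],
                      instruction_id = g$instruction_id[1],
                      instruction_type = g$instruction_type[1],
                      role = g$role[1],
                      n_fragments = max(g$fragment_ordinal),
                      stringsAsFactors = FALSE)
    for (m in measures) out[[m]] <- mean(g[[m]], na.rm = TRUE)
    out
  })
  agg <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  if (!is.null(tier_units)) {
    idx <- match(paste(agg$interaction_id, agg$instruction_id),
                 paste(tier_units$interaction_id, tier_units$instruction_id))
    agg$n_fragments <- tier_units$n_fragments[idx]
  }
  agg
}
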