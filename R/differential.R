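# Differential fitness: per-gene mixed-effects regression of fitness on
# sample type with design covariates, a residual-normality gate, BH FDR
# control, and effect classification.

#' Fit the per-gene fitness regression for one habitat-vs-soil contrast
#'
#' Fits \code{fitness ~ sample_type + auxiliary_community + harvest_day +
#' (1 | flat)} on the samples of the contrast habitat and the soil reference.
#' Constant covariates are dropped. The sample-type coefficient is the log2
#' fold change of mutant abundance in the habitat relative to soil; its
#' p-value comes from a likelihood-ratio test against the model without
#' sample type. When the flat (random-intercept) variance estimate is
#' essentially zero, or only one flat is present, the model degrades to
#' ordinary least squares and the coefficient t-test supplies the p-value.
#'
#' @param y Named numeric vector: one gene's fitness per sample
#'   (names = sample ids).
#' @param design Design table.
#' @param contrast A plant habitat to test against soil.
#' @param re_tol Random-effect variance below which the fit degrades to OLS.
#' @return A list: \code{log2FC}, \code{p_value}, \code{residuals},
#'   \code{flat_variance}, \code{method} ("lmm" or "ols"), \code{skipped}
#'   (logical) and, when skipped, \code{reason}.
#' @export
fit_gene_model <- function(y, design, contrast, re_tol = 1e-8) {
  .check_design(design)
  if (!contrast %in% plant_habitats()) {
    stop("contrast must be one of: ", paste(plant_habitats(), collapse = ", "),
         call. = FALSE)
  }
  sub <- design[design$habitat %in% c("soil", contrast), , drop = FALSE]
  sub <- sub[sub$sample_id %in% names(y), , drop = FALSE]
  fit_y <- y[sub$sample_id]
  usable <- is.finite(fit_y)
  sub <- sub[usable, , drop = FALSE]
  fit_y <- fit_y[usable]
  n_group <- table(factor(sub$habitat, levels = c("soil", contrast)))
  if (nrow(sub) < 4L || any(n_group < 2L)) {
    return(list(skipped = TRUE,
                reason = "fewer than 4 usable samples or <2 per group"))
  }
  dat <- data.frame(
    fitness = fit_y,
    sample_type = factor(sub$habitat, levels = c("soil", contrast)),
    aux = as.numeric(sub$auxiliary_community),
    day = as.numeric(sub$harvest_day),
    flat = factor(sub$flat)
  )
  covs <- c("aux", "day")[c(var(dat$aux) > 0, var(dat$day) > 0)]
  rhs <- paste(c("sample_type", covs), collapse = " + ")
  coef_name <- paste0("sample_type", contrast)

  if (var(dat$fitness) == 0) {
    return(list(log2FC = 0, p_value = 1,
                residuals = rep(0, nrow(dat)),
                flat_variance = 0, method = "ols", skipped = FALSE))
  }

  ols <- function() {
    m <- lm(as.formula(paste("fitness ~", rhs)), data = dat)
    sm <- summary(m)$coefficients
    p <- if (coef_name %in% rownames(sm)) sm[coef_name, "Pr(>|t|)"] else NA_real_
    list(log2FC = unname(coef(m)[coef_name]),
         p_value = if (is.finite(p)) p else 1,
         residuals = unname(residuals(m)),
         flat_variance = 0, method = "ols", skipped = FALSE)
  }

  if (nlevels(dat$flat) < 2L) {
    return(ols())
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  m1 <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(as.formula(paste("fitness ~", rhs, "+ (1 | flat)")),
                 data = dat, REML = FALSE, control = ctrl)
    )),
    error = function(e) NULL
  )
  if (is.null(m1)) {
    return(ols())
  }
  flat_var <- as.numeric(lme4::VarCorr(m1)$flat)
  if (!is.finite(flat_var) || flat_var <= re_tol) {
    res <- ols()
    res$flat_variance <- max(flat_var, 0)
    return(res)
  }
  m0 <- suppressWarnings(suppressMessages(
    lme4::lmer(as.formula(paste("fitness ~",
                                paste(c(covs, "1"), collapse = " + "),
                                "+ (1 | flat)")),
               data = dat, REML = FALSE, control = ctrl)
  ))
  lrt <- suppressMessages(anova(m0, m1))
  p <- lrt[["Pr(>Chisq)"]][2]
  list(log2FC = unname(lme4::fixef(m1)[coef_name]),
       p_value = if (is.finite(p)) p else 1,
       residuals = unname(residuals(m1)),
       flat_variance = flat_var, method = "lmm", skipped = FALSE)
}

.shapiro_p <- function(res) {
  res <- res[is.finite(res)]
  if (length(res) < 3L || length(res) > 5000L) return(NA_real_)
  if (var(res) == 0) return(NA_real_)
  tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
}

#' Residual-normality gate
#'
#' A gene is omitted from the analysis if its model residuals reject
#' normality (Shapiro-Wilk, p < alpha) in any of the fitted contrasts.
#' Contrasts with too few residuals for the test (fewer than 3, or constant
#' residuals) are inapplicable and do not reject; genes with no applicable
#' contrast are retained with a warning.
#'
#' @param normality data.frame with columns \code{gene}, \code{contrast},
#'   \code{normality_p} (NA where the test was inapplicable).
#' @param alpha Rejection level.
#' @return Character vector of retained gene ids.
#' @export
normality_gate <- function(normality, alpha = 0.05) {
  genes <- unique(normality$gene)
  rejected <- unique(normality$gene[
    !is.na(normality$normality_p) & normality$normality_p < alpha
  ])
  applicable <- unique(normality$gene[!is.na(normality$normality_p)])
  inapplicable <- setdiff(genes, applicable)
  if (length(inapplicable)) {
    warning(length(inapplicable),
            " gene(s) had no applicable normality test and were retained",
            call. = FALSE)
  }
  setdiff(genes, rejected)
}

#' Classify gene effects per contrast
#'
#' Applies Benjamini-Hochberg adjustment within each contrast across retained
#' genes, then classifies: \code{association} (mutants depleted in planta;
#' q < \code{q_threshold} and log2FC < -\code{lfc_threshold}),
#' \code{negative_association} (mutants enriched in planta; q <
#' \code{q_threshold} and log2FC > \code{lfc_threshold}), otherwise
#' \code{indifferent}. Genes failing the normality gate carry
#' \code{omitted_nonnormal} and no q-value.
#'
#' @param results data.frame with columns \code{gene}, \code{contrast},
#'   \code{log2FC}, \code{p_value} and logical \code{retained}.
#' @param q_threshold FDR threshold.
#' @param lfc_threshold Absolute log2 fold-change threshold.
#' @return The input with \code{q_value} and \code{category} columns added.
#' @export
classify_effects <- function(results, q_threshold = 0.05, lfc_threshold = 1) {
  results$q_value <- NA_real_
  for (ct in unique(results$contrast)) {
    sel <- results$contrast == ct & results$retained & !is.na(results$p_value)
    results$q_value[sel] <- p.adjust(results$p_value[sel], method = "BH")
  }
  cat_of <- function(q, lfc, retained) {
    if (!retained) return("omitted_nonnormal")
    if (is.na(q) || is.na(lfc)) return("indifferent")
    if (q < q_threshold && lfc < -lfc_threshold) return("association")
    if (q < q_threshold && lfc > lfc_threshold) return("negative_association")
    "indifferent"
  }
  results$category <- mapply(cat_of, results$q_value, results$log2FC,
                             results$retained)
  results
}

#' Differential-fitness analysis across habitats
#'
#' Runs the per-gene regression (\code{\link{fit_gene_model}}) for every gene
#' and every requested habitat-vs-soil contrast, applies the residual
#' normality gate across contrasts (\code{\link{normality_gate}}), adjusts
#' p-values within contrast (BH) and classifies effects
#' (\code{\link{classify_effects}}).
#'
#' @param fitness Gene fitness matrix from \code{\link{gene_fitness}}.
#' @param design Design table.
#' @param contrasts Habitats to test against soil (default: all four plant
#'   habitats present in the design).
#' @param normality_alpha Shapiro-Wilk rejection level for the gate.
#' @param q_threshold,lfc_threshold Classification thresholds.
#' @return data.frame with one row per gene per contrast: \code{gene},
#'   \code{contrast}, \code{log2FC}, \code{p_value}, \code{q_value},
#'   \code{normality_p}, \code{flat_variance}, \code{retained},
#'   \code{category}, \code{n_barcodes}. Genes skipped for insufficient data
#'   are absent and listed in attribute \code{"skipped"}.
#' @export
test_differential_fitness <- function(fitness, design,
                                      contrasts = NULL,
                                      normality_alpha = 0.05,
                                      q_threshold = 0.05,
                                      lfc_threshold = 1) {
  .check_design(design)
  if (is.null(contrasts)) {
    contrasts <- intersect(plant_habitats(), unique(design$habitat))
  }
  genes <- rownames(fitness)
  nb <- attr(fitness, "n_barcodes")
  rows <- vector("list", length(genes) * length(contrasts))
  skipped <- list()
  k <- 0L
  for (g in genes) {
    y <- fitness[g, ]
    for (ct in contrasts) {
      fit <- fit_gene_model(y, design, ct)
      if (isTRUE(fit$skipped)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(gene = g, contrast = ct, reason = fit$reason)
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene = g, contrast = ct,
        log2FC = fit$log2FC, p_value = fit$p_value,
        normality_p = .shapiro_p(fit$residuals),
        flat_variance = fit$flat_variance,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows[seq_len(k)])
  retained_genes <- normality_gate(
    results[, c("gene", "contrast", "normality_p")],
    alpha = normality_alpha
  )
  results$retained <- results$gene %in% retained_genes
  results <- classify_effects(results, q_threshold, lfc_threshold)
  results$n_barcodes <- if (!is.null(nb)) unname(nb[results$gene]) else NA_integer_
  attr(results, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(results, "thresholds") <- c(q = q_threshold, lfc = lfc_threshold,
                                   normality_alpha = normality_alpha)
  results
}
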