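#' Synthetic mean pattern
#'
#' Elementwise average of a face and a body voxel pattern — the model of a
#' part-based whole-person representation with equal part weights.
#'
#' @param face,body Numeric voxel vectors of equal length.
#' @return Numeric voxel vector.
#' @export
synthetic_mean <- function(face, body) {
  if (length(face) != length(body)) {
    stop("face and body patterns differ in length", call. = FALSE)
  }
  (face + body) / 2
}

#' Fisher z transformation of a correlation
#'
#' `atanh(r)` after clipping `r` to `+/-(1 - 1e-7)` so that perfect
#' correlations stay finite.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) > 1)) {
    stop("correlation outside [-1, 1]", call. = FALSE)
  }
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Cross-run correlation between two pattern categories
#'
#' For one subject, ROI and emotion, correlates category A's pattern from
#' one run with category B's pattern from another run, over the three
#' unordered pairs of runs 1-3. For distinct categories both directions of
#' each run pair are used (six correlations); for a category with itself
#' the three unordered pairs are used. Each Pearson correlation is Fisher-z
#' transformed and the mean z (and mean r) is returned. Zero-variance
#' patterns are flagged: the affected comparisons are skipped with a
#' warning and the mean is taken over the rest.
#'
#' @param ds A `pattern_dataset`.
#' @param roi,emotion,subject Cell selectors.
#' @param cat_a,cat_b Categories from [category_levels()].
#' @param runs Runs holding both categories (default 1:3).
#' @return List with `r` (mean correlation), `z` (mean Fisher z), `n_pairs`
#'   (comparisons used), and the selectors.
#' @export
cross_run_correlation <- function(ds, roi, emotion, cat_a, cat_b,
                                  subject = ds$subjects[1], runs = 1:3) {
  pats_a <- lapply(runs, function(r)
    get_category_pattern(ds, subject, r, roi, cat_a, emotion))
  pats_b <- if (identical(cat_a, cat_b)) pats_a else
    lapply(runs, function(r)
      get_category_pattern(ds, subject, r, roi, cat_b, emotion))
  pairs <- utils::combn(seq_along(runs), 2, simplify = FALSE)
  rs <- numeric(0)
  for (p in pairs) {
    combos <- if (identical(cat_a, cat_b)) {
      list(c(p[1], p[2]))
    } else {
      list(c(p[1], p[2]), c(p[2], p[1]))
    }
    for (cmb in combos) {
      va <- pats_a[[cmb[1]]]
      vb <- pats_b[[cmb[2]]]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning(sprintf("zero-variance pattern (%s/%s, %s, %s); pair skipped",
                        cat_a, cat_b, emotion, subject))
        next
      }
      rs <- c(rs, stats::cor(va, vb))
    }
  }
  if (length(rs) == 0) {
    stop("all run pairs had zero-variance patterns", call. = FALSE)
  }
  list(r = mean(rs), z = mean(fisher_z(rs)), n_pairs = length(rs),
       pair = c(cat_a, cat_b), emotion = emotion, roi = roi, subject = subject)
}

#' Representational similarity matrix for one subject
#'
#' 4 x 4 symmetric matrix of mean cross-run Fisher-z correlations among the
#' face, body, person and synthetic-mean categories for one ROI and
#' emotion. The diagonal holds the cross-run same-category reliability.
#'
#' @inheritParams cross_run_correlation
#' @return Numeric 4 x 4 matrix with category dimnames.
#' @export
build_rsm <- function(ds, roi, emotion, subject = ds$subjects[1]) {
  cats <- category_levels()
  m <- matrix(NA_real_, 4, 4, dimnames = list(cats, cats))
  for (i in seq_along(cats)) {
    for (j in i:length(cats)) {
      z <- cross_run_correlation(ds, roi, emotion, cats[i], cats[j],
                                 subject = subject)$z
      m[i, j] <- m[j, i] <- z
    }
  }
  m
}

#' Group-average RSM
#'
#' Elementwise mean of per-subject RSMs. All matrices must share dimnames;
#' missing subjects (NULL entries) raise an error naming the gaps.
#'
#' @param rsms List of 4 x 4 matrices.
#' @export
group_average_rsm <- function(rsms) {
  if (length(rsms) == 0) stop("no RSMs supplied", call. = FALSE)
  missing <- which(vapply(rsms, is.null, logical(1)))
  if (length(missing) > 0) {
    stop("missing RSM for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Reduce(`+`, rsms) / length(rsms)
}

#' Long-format table of cross-run correlations
#'
#' All category-pair cross-run correlations for every subject, ROI and
#' emotion — the input to the category-by-emotion ANOVAs and to RSM
#' construction.
#'
#' @param ds A `pattern_dataset`.
#' @param rois ROIs to include (default all).
#' @return data.frame with columns `subject`, `roi`, `emotion`, `cat_a`,
#'   `cat_b`, `r`, `z`.
#' @export
correlation_table <- function(ds, rois = names(ds$values)) {
  cats <- category_levels()
  combos <- utils::combn(length(cats), 2, simplify = FALSE)
  combos <- c(combos, lapply(seq_along(cats), function(i) c(i, i)))
  rows <- list()
  k <- 0
  for (roi in rois) {
    for (e in emotion_levels()) {
      for (s in ds$subjects) {
        for (cmb in combos) {
          res <- cross_run_correlation(ds, roi, e, cats[cmb[1]], cats[cmb[2]],
                                       subject = s)
          k <- k + 1
          rows[[k]] <- data.frame(subject = s, roi = roi, emotion = e,
                                  cat_a = cats[cmb[1]], cat_b = cats[cmb[2]],
                                  r = res$r, z = res$z,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Category-by-emotion repeated-measures ANOVA on Fisher-z values
#'
#' Compares how well the synthetic mean approximates the whole-person
#' pattern against the face (or body) pattern: a 2 (Category) x 3 (Emotion)
#' within-subject ANOVA on person-face (or person-body) versus
#' person-synthetic z values.
#'
#' @param ztab A [correlation_table()] restricted to one ROI, or any
#'   data.frame with columns `subject`, `emotion`, `cat_a`, `cat_b`, `z`.
#' @param contrast `"person_face_vs_synthetic"` or
#'   `"person_body_vs_synthetic"`.
#' @return data.frame with rows Category, Emotion, Category:Emotion and
#'   columns `effect`, `df1`, `df2`, `F`, `p`. All-constant cells give a
#'   degenerate result (`F = NA`) with a warning.
#' @export
category_emotion_anova <- function(ztab,
                                   contrast = c("person_face_vs_synthetic",
                                                "person_body_vs_synthetic")) {
  contrast <- match.arg(contrast)
  part <- if (contrast == "person_face_vs_synthetic") "face" else "body"
  pick <- function(tab, cat) {
    sel <- (tab$cat_a == "person" & tab$cat_b == cat) |
      (tab$cat_a == cat & tab$cat_b == "person")
    out <- tab[sel, c("subject", "emotion", "z")]
    out$category <- paste0("person_", cat)
    out
  }
  d <- rbind(pick(ztab, part), pick(ztab, "synthetic"))
  counts <- table(d$subject, d$category, d$emotion)
  if (length(counts) == 0 || any(counts != 1)) {
    stop("unbalanced design: need exactly one z per subject x category x emotion",
         call. = FALSE)
  }
  out <- rm_anova_within(d, "category", "emotion", value = "z")
  out$effect <- c("Category", "Emotion", "Category:Emotion")
  out
}

#' Two-way fully within-subject ANOVA
#'
#' Balanced repeated-measures ANOVA with two within-subject factors,
#' fitted with [stats::aov()] using subject-stratified error terms
#' (`Error(subject/(f1*f2))`), without sphericity correction.
#'
#' @param d data.frame with columns `subject`, the two factor columns, and
#'   the response named by `value`.
#' @param f1,f2 Names of the two within-subject factor columns.
#' @param value Response column name.
#' @return data.frame with one row per effect (`f1`, `f2`, interaction)
#'   and columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_within <- function(d, f1, f2, value = "z") {
  d$subject <- factor(d$subject)
  d[[f1]] <- factor(d[[f1]])
  d[[f2]] <- factor(d[[f2]])
  if (nlevels(d[[f1]]) < 2 || nlevels(d[[f2]]) < 2) {
    stop("each within-subject factor needs at least 2 levels", call. = FALSE)
  }
  d$.y <- d[[value]]
  effects <- c(f1, f2, paste0(f1, ":", f2))
  if (stats::var(d$.y) == 0) {
    warning("all cells identical: F undefined")
    return(data.frame(effect = effects, df1 = NA, df2 = NA,
                      F = NA_real_, p = NA_real_))
  }
  form <- stats::as.formula(sprintf(
    ".y ~ %s * %s + Error(subject / (%s * %s))", f1, f2, f1, f2))
  s <- summary(stats::aov(form, data = d))
  grab <- function(term) {
    tab <- s[[paste0("Error: subject:", term)]][[1]]
    i <- which(trimws(rownames(tab)) == term)
    resid <- which(trimws(rownames(tab)) == "Residuals")
    data.frame(df1 = tab$Df[i], df2 = tab$Df[resid],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  cbind(effect = effects, do.call(rbind, lapply(effects, grab)))
}
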