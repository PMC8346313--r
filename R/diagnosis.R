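# Half-up decimal rounding, matching clinical-report percentage style
# (base round() rounds half to even). The tiny epsilon guards against
# values like 93.45 being stored as 93.44999....
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' Echocardiographic CHF positivity flags
#'
#' Applies the rule-based positivity criteria for chronic heart failure
#' on cardiac ultrasound indices, with strict inequalities:
#' LAD > 30 mm positive; LVDD > 55 mm (male) / > 50 mm (female)
#' positive; LVEF < 50% positive. The overall ultrasound call is
#' positive when at least `rule_threshold` of the three indices fire
#' (default 1, i.e. any-of-three).
#'
#' @param p a patient record: a named list or one-row data frame with
#'   `sex` (`"male"`/`"female"`), `lad_mm`, `lvdd_mm`, `lvef_pct`.
#' @param rule_threshold how many positive indices make the overall
#'   call positive (1, 2 or 3).
#' @return A list with logical `lad_positive`, `lvdd_positive`,
#'   `lvef_positive`, `chf_ultrasound_positive`, and integer
#'   `n_positive_indices`.
#' @examples
#' chf_index_flags(list(sex = "male", lad_mm = 40.05,
#'                      lvdd_mm = 56.05, lvef_pct = 60.09))
#' @export
chf_index_flags <- function(p, rule_threshold = 1L) {
  p <- as.list(p)
  need <- c("sex", "lad_mm", "lvdd_mm", "lvef_pct")
  miss <- need[!vapply(need, function(f)
    !is.null(p[[f]]) && !is.na(p[[f]]), logical(1))]
  if (length(miss)) {
    stop("patient record is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sex <- match.arg(p$sex, c("male", "female"))
  rule_threshold <- as.integer(rule_threshold)
  if (rule_threshold < 1L || rule_threshold > 3L) {
    stop("`rule_threshold` must be 1, 2 or 3", call. = FALSE)
  }
  lad_pos <- p$lad_mm > 30
  lvdd_pos <- if (sex == "male") p$lvdd_mm > 55 else p$lvdd_mm > 50
  lvef_pos <- p$lvef_pct < 50
  npos <- sum(lad_pos, lvdd_pos, lvef_pos)
  list(lad_positive = lad_pos, lvdd_positive = lvdd_pos,
       lvef_positive = lvef_pos,
       chf_ultrasound_positive = npos >= rule_threshold,
       n_positive_indices = as.integer(npos))
}

#' AWGS sarcopenia positivity
#'
#' A patient is positive when *any* present criterion fires (strict
#' inequalities): skeletal-muscle index < 7.0 (male) / < 5.4 (female)
#' kg/m^2; grip strength < 26 (male) / < 18 (female) kg; gait speed
#' < 0.8 m/s. Absent measures (`NULL`/`NA`) are skipped; at least one
#' must be present.
#'
#' @param p a patient record: named list or one-row data frame with
#'   `sex` and at least one of `smi_kg_m2`, `grip_kg`, `gait_m_s`.
#' @return Logical flag.
#' @export
sarcopenia_positive <- function(p) {
  p <- as.list(p)
  if (is.null(p$sex) || is.na(p$sex)) {
    stop("patient record is missing: sex", call. = FALSE)
  }
  sex <- match.arg(p$sex, c("male", "female"))
  has <- function(f) !is.null(p[[f]]) && !is.na(p[[f]])
  if (!has("smi_kg_m2") && !has("grip_kg") && !has("gait_m_s")) {
    stop("at least one of smi_kg_m2, grip_kg, gait_m_s must be present",
         call. = FALSE)
  }
  pos <- FALSE
  if (has("smi_kg_m2")) {
    pos <- pos || p$smi_kg_m2 < (if (sex == "male") 7.0 else 5.4)
  }
  if (has("grip_kg")) {
    pos <- pos || p$grip_kg < (if (sex == "male") 26 else 18)
  }
  if (has("gait_m_s")) {
    pos <- pos || p$gait_m_s < 0.8
  }
  pos
}

#' Apply the diagnostic rules to a whole cohort
#'
#' @param cohort a cohort data frame (see [sample_cohort()]).
#' @param rule_threshold passed to [chf_index_flags()].
#' @return The cohort with appended logical columns `lad_positive`,
#'   `lvdd_positive`, `lvef_positive`, `chf_ultrasound_positive`,
#'   `sarcopenia_positive` and integer `n_positive_indices`.
#' @export
diagnose_cohort <- function(cohort, rule_threshold = 1L) {
  flags <- lapply(seq_len(nrow(cohort)), function(i) {
    f <- chf_index_flags(cohort[i, ], rule_threshold)
    f$sarcopenia_positive <- sarcopenia_positive(cohort[i, ])
    f
  })
  cbind(cohort, do.call(rbind, lapply(flags, as.data.frame)))
}

#' Diagnostic concordance percentages
#'
#' `similarity_percent(group_chf, final_chf)` is the agreement between
#' one group's ultrasound CHF calls and the final combined-diagnosis
#' CHF count: `100 * group_chf / final_chf`, rounded half-up to one
#' decimal. `proportion_percent(count, total)` is a plain percentage
#' of a cohort, rounded the same way.
#'
#' @param group_chf CHF count called by one study group (`>= 0`).
#' @param final_chf CHF count of the final combined diagnosis (`>= 1`).
#' @param count,total numerator and denominator counts (`total >= 1`).
#' @return Percentage rounded half-up to one decimal.
#' @examples
#' similarity_percent(215, 230)  # 93.5
#' proportion_percent(200, 259)  # 77.2
#' @export
similarity_percent <- function(group_chf, final_chf) {
  if (final_chf < 1) stop("`final_chf` must be >= 1", call. = FALSE)
  if (group_chf < 0) stop("`group_chf` must be >= 0", call. = FALSE)
  round_half_up(100 * group_chf / final_chf, 1L)
}

#' @rdname similarity_percent
#' @export
proportion_percent <- function(count, total) {
  if (total < 1) stop("`total` must be >= 1", call. = FALSE)
  if (count < 0) stop("`count` must be >= 0", call. = FALSE)
  round_half_up(100 * count / total, 1L)
}

#' Per-group diagnosis count table
#'
#' The tabulated outcome of the study design: for each group (the two
#' ultrasound arms and the final combined diagnosis), how many of the
#' cohort were called CHF and how many other diseases. Each column
#' must sum to the cohort total.
#'
#' @param groups character vector of group labels.
#' @param chf_counts,other_counts integer vectors aligned with
#'   `groups`.
#' @return A `diagnosis_table` data frame with columns `group`,
#'   `chf_count`, `other_count`, `cohort_total`.
#' @export
diagnosis_table <- function(groups, chf_counts, other_counts) {
  if (length(unique(c(length(groups), length(chf_counts),
                      length(other_counts)))) != 1L) {
    stop("`groups`, `chf_counts`, `other_counts` must align",
         call. = FALSE)
  }
  totals <- chf_counts + other_counts
  if (length(unique(totals)) != 1L) {
    stop("every column must sum to the same cohort total", call. = FALSE)
  }
  structure(data.frame(group = groups,
                       chf_count = as.integer(chf_counts),
                       other_count = as.integer(other_counts),
                       cohort_total = as.integer(totals),
                       stringsAsFactors = FALSE),
            class = c("diagnosis_table", "data.frame"))
}

#' Concordance report from a diagnosis table
#'
#' For every non-final group: its CHF proportion of the cohort and its
#' similarity to the final combined diagnosis; plus the final group's
#' own CHF proportion.
#'
#' @param table a [diagnosis_table].
#' @param final_group label of the final-diagnosis column (default
#'   `"final"`).
#' @return A data frame with columns `group`, `chf_count`,
#'   `chf_proportion_pct`, `similarity_to_final_pct` (NA for the final
#'   group itself).
#' @export
concordance_report <- function(table, final_group = "final") {
  stopifnot(inherits(table, "diagnosis_table"))
  if (!final_group %in% table$group) {
    stop(sprintf("no group labelled '%s' in the table", final_group),
         call. = FALSE)
  }
  final_chf <- table$chf_count[table$group == final_group]
  data.frame(
    group = table$group,
    chf_count = table$chf_count,
    chf_proportion_pct = vapply(seq_len(nrow(table)), function(i)
      proportion_percent(table$chf_count[i], table$cohort_total[i]),
      numeric(1)),
    similarity_to_final_pct = vapply(seq_len(nrow(table)), function(i)
      if (table$group[i] == final_group) NA_real_ else
        similarity_percent(table$chf_count[i], final_chf), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Two-group comparison statistics
#'
#' `group_compare(a, b)` is the two independent-samples pooled-variance
#' t-test; `count_compare(m)` the Pearson chi-square test (no
#' continuity correction) on a 2 x 2 count table. Supporting plumbing
#' for simulated-cohort reports.
#'
#' @param a,b numeric samples, each of length `>= 2`.
#' @param m a 2 x 2 matrix of non-negative counts.
#' @return A list with `statistic`, `df`, `p_value`, `method`.
#' @examples
#' group_compare(1:5, 2:6)$statistic  # -1
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate comparison: both samples have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = "two-sample pooled t-test")
}

#' @rdname group_compare
#' @export
count_compare <- function(m) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(2L, 2L)) || any(m < 0)) {
    stop("`m` must be a 2 x 2 matrix of non-negative counts",
         call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, method = "Pearson chi-square (uncorrected)")
}
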