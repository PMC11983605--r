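# Synthetic patient-cohort generator.
#
# Emulates a cross-sectional autoimmune-disorder registry: 13 clinical
# predictors (demographics, history, vitals, blood panel, inflammation
# markers) plus one categorical disease label.  Class-conditional signal is
# planted on the inflammation-related biomarkers so that downstream
# classifiers have something learnable; effect_size = 0 makes every feature
# independent of the label.

AID_CLASSES <- c("RA", "SLE", "MS", "T1D", "Psoriasis", "IBD", "Sjogren", "Other")

AID_CLASS_MIX <- c(
  RA = 0.25, SLE = 0.18, MS = 0.15, T1D = 0.12,
  Psoriasis = 0.10, IBD = 0.08, Sjogren = 0.07, Other = 0.05
)

AID_FEATURES <- data.frame(
  feature = c("age", "gender", "family_history", "symptom_count",
              "blood_pressure", "cholesterol", "bmi", "wbc", "rbc",
              "hemoglobin", "platelets", "crp", "esr", "disease"),
  type = c("continuous", "categorical", "categorical", "continuous",
           "continuous", "continuous", "continuous", "continuous",
           "continuous", "continuous", "continuous", "continuous",
           "continuous", "label"),
  stringsAsFactors = FALSE
)

# Per-class mean-shift directions over the signal-carrying biomarkers.
# Rows are the 8 even-parity codewords of {-1,+1}^4, so any two classes
# differ in at least two coordinates (L2 separation >= 2*sqrt(2) shift
# units per unit effect_size).  CRP and ESR carry the strongest planted
# signal (one shift unit = one baseline SD), mirroring their standing as
# the dominant inflammation markers in autoimmune disease activity.
AID_SIGNATURES <- matrix(
  c( 1,  1,  1,  1,
     1,  1, -1, -1,
     1, -1,  1, -1,
     1, -1, -1,  1,
    -1,  1,  1, -1,
    -1,  1, -1,  1,
    -1, -1,  1,  1,
    -1, -1, -1, -1),
  nrow = 8, byrow = TRUE,
  dimnames = list(AID_CLASSES, c("crp", "esr", "wbc", "symptom_count"))
)

# Physiological baselines for the continuous biomarkers: mean, sd and
# truncation bounds (inverse-CDF truncated-normal sampling), plus the mean
# shift applied per unit of effect_size x signature.
AID_BIOMARKERS <- list(
  blood_pressure = list(mean = 125,    sd = 15,    lower = 80,    upper = 220,  shift = 0),
  cholesterol    = list(mean = 195,    sd = 35,    lower = 90,    upper = 400,  shift = 0),
  bmi            = list(mean = 26,     sd = 4.5,   lower = 14,    upper = 55,   shift = 0),
  wbc            = list(mean = 7500,   sd = 1800,  lower = 1500,  upper = 30000, shift = 1500),
  rbc            = list(mean = 4.9e6,  sd = 5e5,   lower = 2.5e6, upper = 7e6,  shift = 0),
  hemoglobin     = list(mean = 13.8,   sd = 1.6,   lower = 6,     upper = 20,   shift = 0),
  platelets      = list(mean = 275000, sd = 60000, lower = 50000, upper = 1e6,  shift = 0),
  crp            = list(mean = 25,     sd = 8,     lower = 0,     upper = 300,  shift = 8),
  esr            = list(mean = 35,     sd = 12,    lower = 0,     upper = 150,  shift = 12)
)

AID_SYMPTOM_BASE <- 6     # Poisson mean for symptom_count
AID_SYMPTOM_SHIFT <- 2    # symptom_count mean shift per unit effect x signature
AID_FAMILY_HISTORY_P <- 0.35

#' Specify a synthetic autoimmune cohort
#'
#' Builds a validated specification for [generate_cohort()].  Defaults
#' reproduce the study population: 10,000 patients, eight disease classes
#' with prevalences RA 25%, SLE 18%, MS 15%, T1D 12%, Psoriasis 10%,
#' IBD 8%, Sjogren 7% and Other 5%, a 52%/48% women/men split and ages
#' uniform on 18--80 years.
#'
#' @param n Number of patients (non-negative integer).
#' @param seed RNG seed; identical specs generate bitwise-identical cohorts.
#' @param class_mix Named probability vector over disease labels; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param gender_split Probability that a patient is recorded as `"women"`.
#' @param age_range Length-2 numeric, minimum and maximum age in years.
#' @param effect_size Non-negative scalar scaling the class-conditional mean
#'   shifts of the signal biomarkers (crp, esr, wbc, symptom_count).  At 0
#'   every predictor is independent of the disease label; at 1 the planted
#'   shifts equal the documented per-feature shift units (1 SD for CRP/ESR).
#' @param missing_rate Probability in `[0, 1]` that a predictor cell is set
#'   missing (MCAR); the disease label is never masked.
#' @param signatures Optional numeric matrix of per-class mean-shift
#'   directions with one row per class in `class_mix` and columns among
#'   `crp`, `esr`, `wbc`, `symptom_count`.  Defaults to the built-in
#'   even-parity codewords; override to plant custom signal (e.g. a single
#'   informative feature).
#' @return An object of class `"cohort_spec"`.
#' @examples
#' spec <- cohort_spec(n = 500, seed = 42)
#' cohort <- generate_cohort(spec)
#' table(cohort$disease)
#' @export
cohort_spec <- function(n = 10000L, seed = 1L,
                        class_mix = AID_CLASS_MIX,
                        gender_split = 0.52,
                        age_range = c(18, 80),
                        effect_size = 1,
                        missing_rate = 0.05,
                        signatures = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("`n` must be a non-negative integer")
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix)))) {
    stop("`class_mix` must be a named probability vector")
  }
  if (any(class_mix < 0)) stop("`class_mix` probabilities must be >= 0")
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("`class_mix` probabilities must sum to 1 (got ", sum(class_mix), ")")
  }
  if (gender_split < 0 || gender_split > 1) stop("`gender_split` must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop("`missing_rate` must be in [0, 1]")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("`age_range` must be c(min, max) with min < max")
  }
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  if (is.null(signatures)) {
    signatures <- matrix(0, length(class_mix), ncol(AID_SIGNATURES),
                         dimnames = list(names(class_mix), colnames(AID_SIGNATURES)))
    shared <- intersect(names(class_mix), rownames(AID_SIGNATURES))
    signatures[shared, ] <- AID_SIGNATURES[shared, ]
  } else {
    signatures <- as.matrix(signatures)
    if (is.null(rownames(signatures))) rownames(signatures) <- names(class_mix)
    if (!all(names(class_mix) %in% rownames(signatures))) {
      stop("`signatures` must have one row per class in `class_mix`")
    }
    bad <- setdiff(colnames(signatures), colnames(AID_SIGNATURES))
    if (length(bad)) stop("unknown signature feature(s): ", paste(bad, collapse = ", "))
    full <- matrix(0, length(class_mix), ncol(AID_SIGNATURES),
                   dimnames = list(names(class_mix), colnames(AID_SIGNATURES)))
    full[names(class_mix), colnames(signatures)] <- signatures[names(class_mix), , drop = FALSE]
    signatures <- full
  }
  structure(
    list(n = n, seed = as.integer(seed), class_mix = class_mix,
         gender_split = gender_split, age_range = as.numeric(age_range),
         effect_size = effect_size, missing_rate = missing_rate,
         signatures = signatures),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  n:            ", x$n, "\n")
  cat("  seed:         ", x$seed, "\n")
  cat("  classes:      ", paste0(names(x$class_mix), " (",
                                 format(100 * x$class_mix, trim = TRUE), "%)",
                                 collapse = ", "), "\n")
  cat("  gender split: ", 100 * x$gender_split, "% women\n")
  cat("  age range:    ", x$age_range[1], "-", x$age_range[2], "years\n")
  cat("  effect size:  ", x$effect_size, "\n")
  cat("  missing rate: ", x$missing_rate, "\n")
  invisible(x)
}

# Truncated-normal draws by inverse-CDF; one uniform per value keeps the
# RNG stream length independent of the truncation bounds.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n` patient records.  Disease labels are i.i.d. from the class
#' mix; gender and family history are Bernoulli; age is uniform on the age
#' range; continuous biomarkers come from truncated normal distributions
#' whose means are shifted by `effect_size` times the per-class signature;
#' symptom counts are Poisson.  Missingness is injected MCAR at
#' `spec$missing_rate` on the predictors only.  Identical specs yield
#' bitwise-identical tables.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `"aid_cohort"` with the 13 predictors and
#'   the `disease` factor, in registry column order.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  n <- spec$n
  classes <- names(spec$class_mix)
  with_seed(spec$seed, {
    disease <- if (n > 0) {
      sample(classes, n, replace = TRUE, prob = spec$class_mix)
    } else character(0)
    sig <- spec$signatures[disease, , drop = FALSE] * spec$effect_size

    age <- runif(n, spec$age_range[1], spec$age_range[2])
    gender <- ifelse(runif(n) < spec$gender_split, "women", "men")
    family_history <- ifelse(runif(n) < AID_FAMILY_HISTORY_P, "yes", "no")
    lambda <- pmax(0.3, AID_SYMPTOM_BASE + AID_SYMPTOM_SHIFT * sig[, "symptom_count"])
    symptom_count <- if (n > 0) rpois(n, lambda) else integer(0)

    biom <- lapply(names(AID_BIOMARKERS), function(f) {
      p <- AID_BIOMARKERS[[f]]
      shift <- if (f %in% colnames(sig) && p$shift != 0) p$shift * sig[, f] else 0
      rtruncnorm(n, p$mean + shift, p$sd, p$lower, p$upper)
    })
    names(biom) <- names(AID_BIOMARKERS)

    tab <- data.frame(
      age = age, gender = gender, family_history = family_history,
      symptom_count = as.numeric(symptom_count),
      blood_pressure = biom$blood_pressure, cholesterol = biom$cholesterol,
      bmi = biom$bmi, wbc = biom$wbc, rbc = biom$rbc,
      hemoglobin = biom$hemoglobin, platelets = biom$platelets,
      crp = biom$crp, esr = biom$esr,
      disease = factor(disease, levels = classes),
      stringsAsFactors = FALSE
    )
    if (n == 0) {
      tab <- tab[0, , drop = FALSE]
      tab$disease <- factor(character(0), levels = classes)
    }
    if (spec$missing_rate > 0 && n > 0) {
      tab <- mask_cells(tab, spec$missing_rate)
    }
    class(tab) <- c("aid_cohort", "data.frame")
    attr(tab, "spec") <- spec
    tab
  })
}

# Bernoulli-mask every predictor cell in place using the current RNG stream.
mask_cells <- function(table, rate) {
  predictors <- setdiff(cohort_predictors(table), c("patient_id", "visit"))
  for (f in predictors) {
    hit <- runif(nrow(table)) < rate
    table[[f]][hit] <- NA
  }
  table
}

cohort_predictors <- function(table) {
  setdiff(names(table), "disease")
}

#' Inject missingness into a cohort
#'
#' Independently sets each predictor cell missing with probability `rate`
#' (missing completely at random).  The disease label is never masked.
#'
#' @param table A cohort `data.frame`.
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]")
  if (rate == 0) return(table)
  with_seed(seed, mask_cells(table, rate))
}

#' Expand a cross-sectional cohort into longitudinal visits
#'
#' Each patient is replicated into `n_visits` ordered visit records.  Visit
#' 1 equals the baseline record; subsequent visits apply a seeded random-walk
#' drift of magnitude `drift` (in baseline-SD units per visit) to the
#' continuous biomarkers.  The disease label is constant across visits.  The
#' source registry is cross-sectional, so this expansion is a modelling
#' device for exercising the recurrent stage, not an observed process.
#'
#' @param table A cohort `data.frame`.
#' @param n_visits Number of visits per patient (>= 1).
#' @param seed RNG seed.
#' @param drift Random-walk SD per visit, in units of each biomarker's
#'   baseline SD.
#' @return A `data.frame` with `patient_id` and `visit` columns prepended;
#'   for `n_visits = 1` the feature columns equal the input table.
#' @export
make_visits <- function(table, n_visits, seed = 1L, drift = 0.05) {
  n_visits <- as.integer(n_visits)
  if (is.na(n_visits) || n_visits < 1) stop("`n_visits` must be >= 1")
  n <- nrow(table)
  drift_feats <- intersect(names(AID_BIOMARKERS), names(table))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_visits), function(v) {
      visit <- as.data.frame(table)
      visit <- cbind(patient_id = seq_len(n), visit = v, visit)
      visit
    }))
    out <- out[order(out$patient_id, out$visit), , drop = FALSE]
    rownames(out) <- NULL
    if (n_visits > 1 && drift > 0 && n > 0) {
      for (f in drift_feats) {
        s <- AID_BIOMARKERS[[f]]$sd * drift
        steps <- matrix(rnorm(n * (n_visits - 1), 0, s), n, n_visits - 1)
        # apply() drops dims when there is a single step column
        walk <- cbind(0, if (n_visits == 2) steps else t(apply(steps, 1, cumsum)))
        out[[f]] <- out[[f]] + as.vector(t(walk))
      }
    }
    class(out) <- c("aid_cohort_visits", "data.frame")
    out
  })
}

#' Write / read a cohort CSV
#'
#' UTF-8, comma-delimited, header row of registry feature names; missing
#' cells are serialized as empty fields.
#'
#' @param table A cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   an `"aid_cohort"` data frame with the disease label as a factor.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param levels Optional disease levels for the factor; defaults to the
#'   levels observed in the file, or the registry classes when all are seen.
#' @export
read_cohort <- function(path, levels = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
  if ("disease" %in% names(tab)) {
    if (is.null(levels)) {
      seen <- unique(tab$disease)
      levels <- if (all(seen %in% AID_CLASSES)) AID_CLASSES else sort(seen)
    }
    tab$disease <- factor(tab$disease, levels = levels)
  }
  class(tab) <- c("aid_cohort", "data.frame")
  tab
}
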