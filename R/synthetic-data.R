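# Synthetic paired-cohort generator. Emulates the statistical structure the
# downstream analysis assumes: paired cancer/non-cancer samples split across
# two instruments, lipid features with category-level abundance shifts,
# left-censored (missing-not-at-random) intensities, isotopologue peaks with
# geometrically decaying intensity, and partial assignment ambiguity.

.LIPID_CATEGORIES <- c("FA", "GP", "PR", "SP", "ST")

#' Simulation configuration for a synthetic paired lipidomics study
#'
#' Builds and validates the configuration consumed by [generate_study()].
#' Defaults describe the emulated study design: 40 patients with one cancer
#' and one non-cancer sample each, acquired on one of two instruments per
#' patient, lipid-category composition matching the observed single-category
#' universe (FA 12 : GP 205 : PR 5 : SP 281 : ST 23), and category-level
#' log2 shifts in cancer of +2 for sterols, -1 for glycerophospholipids and
#' +1 for sphingolipids at or above m/z 700.
#'
#' @param n_patients Number of patients; each contributes one cancer and one
#'   non-cancer sample.
#' @param n_features Number of elemental molecular formulas (EMFs) simulated.
#'   Each EMF emits `isotopologue_count` isotopologue features.
#' @param frac_category Named proportions over FA, GP, PR, SP, ST. May sum to
#'   less than 1; the remainder is generated as "not-lipid" features.
#' @param mz_range Numeric length-2: m/z interval for monoisotopic ion m/z.
#'   Must lie within (150, 1605].
#' @param effect_log2fc Named log2 shifts in cancer, keyed by annotation
#'   (any of FA, GP, PR, SP, SP-low, SP-high, ST). For SP features the
#'   SP-low/SP-high entry (by monoisotopic ion m/z vs `mz_split`) takes
#'   precedence over a plain SP entry.
#' @param mz_split m/z boundary separating low- from high-m/z sphingolipids.
#' @param sigma_patient,sigma_instrument,sigma_noise Log2-scale standard
#'   deviations of the per-patient, per-instrument and residual effects.
#' @param mu_baseline,sigma_baseline Mean and sd of per-feature baseline
#'   log2 abundance.
#' @param censor_quantile Proportion in [0, 1): per-class detection threshold
#'   set at this quantile of the class's latent log2 abundances; values
#'   strictly below are censored (missing).
#' @param ambiguity_rate Proportion of emitted peaks that carry a second,
#'   decoy candidate EMF.
#' @param multi_class_rate Proportion of lipid EMFs whose classifier label is
#'   flagged as multiply categorized (excluded from enrichment downstream).
#' @param isotopologue_count Isotopologue peaks emitted per present EMF
#'   (m+0, m+1, ...).
#' @param isotopologue_ratio Intensity ratio between consecutive
#'   isotopologues.
#' @param mz_jitter_ppm Standard deviation of the per-peak mass-measurement
#'   error, in ppm.
#' @param frac_instrument1 Proportion of patients acquired on instrument
#'   "Fusion1" (both samples of a patient share the instrument).
#' @param statin_rate Probability a patient is flagged as a statin user.
#' @param seed Integer RNG seed; the whole study is a deterministic function
#'   of the configuration.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 40L,
                       n_features = 300L,
                       frac_category = c(FA = 12, GP = 205, PR = 5, SP = 281, ST = 23) / 526,
                       mz_range = c(200, 1600),
                       effect_log2fc = c(ST = 2, GP = -1, "SP-high" = 1),
                       mz_split = 700,
                       sigma_patient = 0.5,
                       sigma_instrument = 1,
                       sigma_noise = 0.3,
                       mu_baseline = 20,
                       sigma_baseline = 2,
                       censor_quantile = 0.25,
                       ambiguity_rate = 0.2,
                       multi_class_rate = 0.05,
                       isotopologue_count = 3L,
                       isotopologue_ratio = 0.3,
                       mz_jitter_ppm = 1,
                       frac_instrument1 = 53 / 93,
                       statin_rate = 1 / 3,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_features = as.integer(n_features),
    frac_category = frac_category, mz_range = as.numeric(mz_range),
    effect_log2fc = effect_log2fc, mz_split = mz_split,
    sigma_patient = sigma_patient, sigma_instrument = sigma_instrument,
    sigma_noise = sigma_noise, mu_baseline = mu_baseline,
    sigma_baseline = sigma_baseline, censor_quantile = censor_quantile,
    ambiguity_rate = ambiguity_rate, multi_class_rate = multi_class_rate,
    isotopologue_count = as.integer(isotopologue_count),
    isotopologue_ratio = isotopologue_ratio, mz_jitter_ppm = mz_jitter_ppm,
    frac_instrument1 = frac_instrument1, statin_rate = statin_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1L || cfg$n_features < 1L) {
    stop("n_patients and n_features must be positive")
  }
  fc <- cfg$frac_category
  if (is.null(names(fc)) || !all(names(fc) %in% .LIPID_CATEGORIES)) {
    stop("frac_category must be named by lipid category (FA, GP, PR, SP, ST)")
  }
  if (any(fc < 0) || any(fc > 1) || sum(fc) > 1 + 1e-9) {
    stop("frac_category proportions must be in [0, 1] and sum to at most 1")
  }
  if (length(cfg$mz_range) != 2L || cfg$mz_range[1] >= cfg$mz_range[2] ||
      cfg$mz_range[1] <= 150 || cfg$mz_range[2] > 1605) {
    stop("mz_range must be an increasing interval within (150, 1605]")
  }
  sig <- c(cfg$sigma_patient, cfg$sigma_instrument, cfg$sigma_noise, cfg$sigma_baseline)
  if (any(sig < 0)) stop("standard deviations must be non-negative")
  for (p in c("censor_quantile", "ambiguity_rate", "multi_class_rate", "statin_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] >= 1 + (p != "censor_quantile")) {
      stop(p, " must lie in [0, 1)")
    }
    if (cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$isotopologue_count < 1L) stop("isotopologue_count must be >= 1")
  if (cfg$isotopologue_ratio < 0 || cfg$isotopologue_ratio >= 1) {
    stop("isotopologue_ratio must lie in [0, 1)")
  }
  invisible(cfg)
}

# Build a lipid-like CHNOP formula whose [M+adduct]+ m/z is close to a
# target, respecting the element caps C130 H230 N7 O28 P3.
.random_emf <- function(mz_target, adduct) {
  neutral <- mz_target - unname(.ADDUCT_MASS[adduct])
  for (attempt in 1:20) {
    n <- sample(0:2, 1)
    o <- sample(2:12, 1)
    p <- sample(0:1, 1, prob = c(0.7, 0.3))
    rest <- unname(neutral - n * .ELEMENT_MASS["N"] - o * .ELEMENT_MASS["O"] -
                     p * .ELEMENT_MASS["P"])
    # carbon skeleton with roughly H = 1.8 C (lipid-like saturation)
    cc <- unname(round(rest / (.ELEMENT_MASS["C"] + 1.8 * .ELEMENT_MASS["H"])))
    if (cc < 5 || cc > .ELEMENT_CAPS["C"]) next
    h <- unname(round((rest - cc * .ELEMENT_MASS["C"]) / .ELEMENT_MASS["H"]))
    if (h < 2 || h > min(.ELEMENT_CAPS["H"], 2 * cc + 2 + n)) next
    counts <- c(C = cc, H = h, N = n, O = o, P = p)
    if (ion_mz(counts, 0L, adduct) > 1605) next
    return(counts)
  }
  # fallback: plain saturated hydrocarbon-ester backbone
  cc <- max(5, min(.ELEMENT_CAPS["C"], round(neutral / 14)))
  c(C = cc, H = min(2 * cc, .ELEMENT_CAPS["H"]), N = 0, O = 2, P = 0)
}

# Deterministic decoy formula: swap CH2 <-> N, which preserves nominal mass
# (the closest perturbation available under the CHNOP element caps).
.decoy_emf <- function(counts) {
  if (counts["N"] < .ELEMENT_CAPS["N"] && counts["C"] > 5 && counts["H"] > 4) {
    counts["C"] <- counts["C"] - 1
    counts["H"] <- counts["H"] - 2
    counts["N"] <- counts["N"] + 1
  } else if (counts["N"] >= 1) {
    counts["N"] <- counts["N"] - 1
    counts["C"] <- counts["C"] + 1
    counts["H"] <- counts["H"] + 2
  } else {
    counts["H"] <- counts["H"] - 2  # one degree of unsaturation off
  }
  counts
}

#' Generate a synthetic paired lipidomics study
#'
#' Simulates per-sample assigned peak lists, sample metadata and a
#' ground-truth table. Each feature's latent log2 abundance in a sample is
#' `baseline + class effect + patient effect + instrument effect + noise`;
#' values strictly below the class-specific censoring threshold (the
#' `censor_quantile` quantile of that class's latent values) are omitted,
#' giving missing-not-at-random sparsity. Each surviving EMF emits
#' isotopologue peaks with geometrically decaying intensity, and a fraction
#' `ambiguity_rate` of peaks carries a decoy candidate EMF.
#'
#' @param config A [sim_config()].
#' @return Object of class `"lipid_study"`: list with `peaklists` (named list
#'   of per-sample assigned peak tables), `metadata` (sample table),
#'   `features` (per-EMF truth), `thresholds` (per-class censoring threshold,
#'   log2 scale) and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  P <- config$n_patients
  nf <- config$n_features

  ## ---- samples -------------------------------------------------------
  patient_id <- sprintf("P%03d", seq_len(P))
  n1 <- min(max(round(config$frac_instrument1 * P), 1L), max(P - 1L, 1L))
  instr_patient <- rep("Fusion2", P)
  instr_patient[sample.int(P, n1)] <- "Fusion1"
  statin <- stats::runif(P) < config$statin_rate
  metadata <- data.frame(
    sample_id = c(paste0(patient_id, "_C"), paste0(patient_id, "_N")),
    patient_id = rep(patient_id, 2),
    class = rep(c("cancer", "non-cancer"), each = P),
    instrument = rep(instr_patient, 2),
    statin = rep(statin, 2),
    stringsAsFactors = FALSE
  )
  metadata <- metadata[order(metadata$patient_id, metadata$class), ]
  rownames(metadata) <- NULL
  ns <- nrow(metadata)

  ## ---- features ------------------------------------------------------
  fc <- config$frac_category
  probs <- c(fc, "not-lipid" = max(0, 1 - sum(fc)))
  probs <- probs[probs > 0]
  category <- sample(names(probs), nf, replace = TRUE, prob = probs)
  adduct <- sample(names(.ADDUCT_MASS), nf, replace = TRUE,
                   prob = c(0.70, 0.15, 0.10, 0.05))
  mz_target <- stats::runif(nf, config$mz_range[1], config$mz_range[2])
  emf_counts <- vector("list", nf)
  emf <- character(nf)
  mz0 <- numeric(nf)
  for (f in seq_len(nf)) {
    emf_counts[[f]] <- .random_emf(mz_target[f], adduct[f])
    emf[f] <- format_emf(emf_counts[[f]])
    mz0[f] <- ion_mz(emf_counts[[f]], 0L, adduct[f])
  }
  # collapse accidental duplicate (EMF, adduct) pairs by regenerating once
  dup <- duplicated(paste(emf, adduct))
  for (f in which(dup)) {
    emf_counts[[f]] <- .random_emf(stats::runif(1, config$mz_range[1], config$mz_range[2]),
                                   adduct[f])
    emf[f] <- format_emf(emf_counts[[f]])
    mz0[f] <- ion_mz(emf_counts[[f]], 0L, adduct[f])
  }
  keep <- !duplicated(paste(emf, adduct))
  if (!all(keep)) {
    nf <- sum(keep)
    category <- category[keep]; adduct <- adduct[keep]
    emf_counts <- emf_counts[keep]; emf <- emf[keep]; mz0 <- mz0[keep]
  }
  multi_class <- category %in% .LIPID_CATEGORIES &
    stats::runif(nf) < config$multi_class_rate

  eff_map <- config$effect_log2fc
  annot <- category
  is_sp <- category == "SP"
  annot[is_sp & mz0 >= config$mz_split] <- "SP-high"
  annot[is_sp & mz0 < config$mz_split] <- "SP-low"
  effect <- numeric(nf)
  for (f in seq_len(nf)) {
    e <- if (annot[f] %in% names(eff_map)) {
      eff_map[[annot[f]]]
    } else if (is_sp[f] && "SP" %in% names(eff_map)) {
      eff_map[["SP"]]
    } else 0
    effect[f] <- e
  }

  decoy <- character(nf)
  decoy_category <- character(nf)
  for (f in seq_len(nf)) {
    decoy[f] <- format_emf(.decoy_emf(emf_counts[[f]]))
    decoy_category[f] <- sample(.LIPID_CATEGORIES, 1)
  }

  features <- data.frame(
    emf = emf, adduct = adduct, mz = mz0, category = category,
    annotation = annot, multi_class = multi_class,
    true_log2fc = effect, differential = abs(effect) > 0,
    decoy_emf = decoy, stringsAsFactors = FALSE
  )

  ## ---- latent abundance ----------------------------------------------
  baseline <- stats::rnorm(nf, config$mu_baseline, config$sigma_baseline)
  pat_eff <- matrix(stats::rnorm(nf * P, 0, config$sigma_patient), nf, P,
                    dimnames = list(NULL, patient_id))
  ins_eff <- stats::rnorm(nf, 0, config$sigma_instrument)  # Fusion2 - Fusion1
  latent <- matrix(0, nf, ns, dimnames = list(NULL, metadata$sample_id))
  for (s in seq_len(ns)) {
    p <- metadata$patient_id[s]
    latent[, s] <- baseline +
      (metadata$class[s] == "cancer") * effect +
      pat_eff[, p] +
      (metadata$instrument[s] == "Fusion2") * ins_eff +
      if (config$sigma_noise > 0) stats::rnorm(nf, 0, config$sigma_noise) else 0
  }

  thresholds <- vapply(c("cancer", "non-cancer"), function(cl) {
    stats::quantile(latent[, metadata$class == cl], config$censor_quantile,
                    names = FALSE, type = 7)
  }, numeric(1))
  present <- latent >= matrix(thresholds[metadata$class], nf, ns, byrow = TRUE)

  ## ---- peak lists ----------------------------------------------------
  K <- config$isotopologue_count
  iso_idx <- seq_len(K) - 1L
  iso_mz <- outer(mz0, iso_idx * .C13_DELTA, "+")   # nf x K theoretical m/z
  peaklists <- vector("list", ns)
  names(peaklists) <- metadata$sample_id
  for (s in seq_len(ns)) {
    fs <- which(present[, s])
    if (length(fs) == 0L) {
      peaklists[[s]] <- .empty_peaklist()
      next
    }
    npk <- length(fs) * K
    f_rep <- rep(fs, each = K)
    k_rep <- rep(iso_idx, times = length(fs))
    theo <- iso_mz[cbind(f_rep, k_rep + 1L)]
    mz_obs <- theo * (1 + stats::rnorm(npk, 0, config$mz_jitter_ppm * 1e-6))
    inten <- 2^latent[cbind(f_rep, rep(s, npk))] * config$isotopologue_ratio^k_rep
    pk <- data.frame(
      peak_id = seq_len(npk), mz = mz_obs, intensity = inten,
      emf = emf[f_rep], isotopologue = k_rep, adduct = adduct[f_rep],
      category = category[f_rep], multi_class = multi_class[f_rep],
      stringsAsFactors = FALSE
    )
    amb <- stats::runif(npk) < config$ambiguity_rate
    if (any(amb)) {
      dk <- pk[amb, , drop = FALSE]
      dk$emf <- decoy[f_rep[amb]]
      dk$category <- decoy_category[f_rep[amb]]
      dk$multi_class <- FALSE
      pk <- rbind(pk, dk)
      pk <- pk[order(pk$peak_id), , drop = FALSE]
      rownames(pk) <- NULL
    }
    peaklists[[s]] <- pk
  }

  structure(list(peaklists = peaklists, metadata = metadata,
                 features = features, thresholds = thresholds,
                 config = config),
            class = "lipid_study")
}

.empty_peaklist <- function() {
  data.frame(peak_id = integer(), mz = numeric(), intensity = numeric(),
             emf = character(), isotopologue = integer(), adduct = character(),
             category = character(), multi_class = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.lipid_study <- function(x, ...) {
  cat("Synthetic paired lipidomics study\n")
  cat(sprintf("  %d patients, %d samples, %d EMFs (x%d isotopologues)\n",
              x$config$n_patients, nrow(x$metadata), nrow(x$features),
              x$config$isotopologue_count))
  cat(sprintf("  censoring thresholds (log2): cancer %.2f, non-cancer %.2f\n",
              x$thresholds["cancer"], x$thresholds["non-cancer"]))
  invisible(x)
}

#' Ground-truth feature table of a synthetic study
#'
#' Expands the per-EMF truth to the isotopologue-level features the
#' correspondence step recovers: one row per (EMF, isotopologue, adduct)
#' with its theoretical ion m/z, true category, true log2 effect and
#' differential flag (`|true_log2fc| > 0`).
#'
#' @param study A `lipid_study` from [generate_study()].
#' @return Data frame keyed by `feature_id` (`EMF|isotopologue|adduct`).
#' @export
truth_table <- function(study) {
  stopifnot(inherits(study, "lipid_study"))
  ft <- study$features
  K <- study$config$isotopologue_count
  idx <- rep(seq_len(nrow(ft)), each = K)
  iso <- rep(seq_len(K) - 1L, times = nrow(ft))
  out <- data.frame(
    feature_id = paste(ft$emf[idx], iso, ft$adduct[idx], sep = "|"),
    emf = ft$emf[idx], isotopologue = iso, adduct = ft$adduct[idx],
    mz = ft$mz[idx] + iso * .C13_DELTA,
    category = ft$category[idx], multi_class = ft$multi_class[idx],
    true_log2fc = ft$true_log2fc[idx],
    differential = ft$differential[idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a synthetic study to delimited peak-list and metadata files
#'
#' One tab-delimited peak-list file per sample (`<sample_id>.tsv` with
#' columns `peak_id`, `mz`, `intensity`, `assignments`; candidate
#' assignments are `;`-joined `EMF|isotopologue|adduct|category|multi`
#' strings) plus `metadata.tsv`. Numeric columns are written with full
#' precision so that [read_peaklists()] round-trips exactly.
#'
#' @param study A `lipid_study`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_peaklists <- function(study, dir) {
  stopifnot(inherits(study, "lipid_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sid in names(study$peaklists)) {
    pk <- study$peaklists[[sid]]
    ann <- paste(pk$emf, pk$isotopologue, pk$adduct, pk$category,
                 as.integer(pk$multi_class), sep = "|")
    agg <- if (nrow(pk)) {
      stats::aggregate(ann, by = list(peak_id = pk$peak_id),
                       FUN = paste, collapse = ";")
    } else data.frame(peak_id = integer(), x = character())
    first <- pk[!duplicated(pk$peak_id), c("peak_id", "mz", "intensity")]
    tab <- merge(first, agg, by = "peak_id", sort = TRUE)
    names(tab)[4] <- "assignments"
    tab$mz <- sprintf("%.17g", tab$mz)
    tab$intensity <- sprintf("%.17g", tab$intensity)
    path <- file.path(dir, paste0(sid, ".tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  mpath <- file.path(dir, "metadata.tsv")
  utils::write.table(study$metadata, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, mpath))
}

#' Read peak-list and metadata files written by [write_peaklists()]
#'
#' @param dir Directory containing `<sample_id>.tsv` files and
#'   `metadata.tsv`.
#' @return List with `peaklists` (named list of long-format assigned peak
#'   tables, one row per candidate) and `metadata`.
#' @export
read_peaklists <- function(dir) {
  mpath <- file.path(dir, "metadata.tsv")
  if (!file.exists(mpath)) stop("metadata.tsv not found in ", dir)
  metadata <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  metadata$statin <- as.logical(metadata$statin)
  peaklists <- vector("list", nrow(metadata))
  names(peaklists) <- metadata$sample_id
  for (sid in metadata$sample_id) {
    path <- file.path(dir, paste0(sid, ".tsv"))
    if (!file.exists(path)) stop("peak list for sample ", sid, " not found")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c("integer", "numeric", "numeric",
                                            "character"))
    if (nrow(tab) == 0L) {
      peaklists[[sid]] <- .empty_peaklist()
      next
    }
    cand <- strsplit(tab$assignments, ";", fixed = TRUE)
    ncand <- lengths(cand)
    parts <- do.call(rbind, strsplit(unlist(cand), "|", fixed = TRUE))
    peaklists[[sid]] <- data.frame(
      peak_id = rep(tab$peak_id, ncand),
      mz = rep(tab$mz, ncand),
      intensity = rep(tab$intensity, ncand),
      emf = parts[, 1],
      isotopologue = as.integer(parts[, 2]),
      adduct = parts[, 3],
      category = parts[, 4],
      multi_class = parts[, 5] == "1",
      stringsAsFactors = FALSE
    )
  }
  list(peaklists = peaklists, metadata = metadata)
}
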