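#' Default genus pool for synthetic dam-litter datasets
#'
#' The culturable genera reported from the study system (rectal,
#' meconium, vaginal and mammary-secretion samples of dams and
#' puppies): enteric Gram-negatives, streptococci/enterococci,
#' staphylococci, clostridia and common environmental genera.
#'
#' @return character vector of genus names.
#' @export
default_genus_pool <- function() {
  c("Aerococcus", "Clostridium", "Enterobacter", "Enterococcus",
    "Escherichia", "Klebsiella", "Leclercia", "Proteus",
    "Pseudomonas", "Psychrobacter", "Staphylococcus", "Streptococcus")
}

#' Configuration for the synthetic dam-litter generator
#'
#' Encodes the study design the generator emulates: `n_families`
#' dam-litter units, four sampling times (T0/T2/T30/T60), dams
#' contributing rectal swabs at every time plus vaginal and mammary
#' secretion (colostrum at T0, milk at T2), puppies contributing
#' meconium at T0 and rectal swabs afterwards. Each family has a
#' latent binary genus profile; every sample is the profile with each
#' genus independently flipped at the time point's flip rate, so a
#' decreasing flip schedule makes within-family heterogeneity shrink
#' over time (the "convergent" preset). The "null" preset holds the
#' flip rate constant (0.25) and removes meconium dropout so all time
#' points are exchangeable.
#'
#' @param n_families number of dam-litter units (default 6).
#' @param litter_sizes litter sizes; used as-is when the length equals
#'   `n_families` (default 8, 6, 4, 8, 7, 3), otherwise sampled
#'   uniformly from the supplied pool (so `3:8` acts as a range).
#' @param genus_pool character vector of genera (default
#'   [default_genus_pool()]).
#' @param baseline_prevalence per-genus probability of membership in a
#'   family profile (default 0.4).
#' @param flip_rates named per-time-point probability that a genus
#'   state is flipped in a sample (default T0 0.40, T2 0.30, T30 0.15,
#'   T60 0.10).
#' @param meconium_dropout extra probability that a genus present in a
#'   meconium sample is missed (default 0.5; meconium is markedly
#'   sparser than later rectal swabs).
#' @param include_dam_matrices generate vaginal and mammary-secretion
#'   samples for dams (default `TRUE`).
#' @param shared_core genera forced present in every family profile
#'   (default none).
#' @param seed RNG seed (default 1).
#' @param preset `"convergent"` (the defaults) or `"null"`.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_families = 6,
                             litter_sizes = c(8, 6, 4, 8, 7, 3),
                             genus_pool = default_genus_pool(),
                             baseline_prevalence = 0.4,
                             flip_rates = c(T0 = 0.40, T2 = 0.30,
                                            T30 = 0.15, T60 = 0.10),
                             meconium_dropout = 0.5,
                             include_dam_matrices = TRUE,
                             shared_core = character(0),
                             seed = 1,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("convergent", "null"))
    if (preset == "null") {
      flip_rates <- c(T0 = 0.25, T2 = 0.25, T30 = 0.25, T60 = 0.25)
      meconium_dropout <- 0
    }
  } else {
    preset <- "convergent"
  }
  if (length(genus_pool) == 0L) stop("genus_pool is empty", call. = FALSE)
  if (anyDuplicated(genus_pool)) stop("genus_pool has duplicates",
                                      call. = FALSE)
  stopifnot(n_families >= 1, all(litter_sizes >= 1),
            baseline_prevalence > 0, baseline_prevalence < 1,
            meconium_dropout >= 0, meconium_dropout < 1)
  if (!all(tp_levels() %in% names(flip_rates))) {
    stop("flip_rates must name all of ",
         paste(tp_levels(), collapse = ", "), call. = FALSE)
  }
  flip_rates <- flip_rates[tp_levels()]
  if (any(flip_rates < 0) || any(flip_rates > 0.5)) {
    stop("flip rates must lie in [0, 0.5]", call. = FALSE)
  }
  if (preset == "convergent" && is.unsorted(rev(flip_rates))) {
    stop("convergent preset requires non-increasing flip rates",
         call. = FALSE)
  }
  miss <- setdiff(shared_core, genus_pool)
  if (length(miss)) {
    stop("shared_core genera not in pool: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(n_families = n_families, litter_sizes = litter_sizes,
                 genus_pool = genus_pool,
                 baseline_prevalence = baseline_prevalence,
                 flip_rates = flip_rates,
                 meconium_dropout = meconium_dropout,
                 include_dam_matrices = include_dam_matrices,
                 shared_core = shared_core, seed = seed, preset = preset),
            class = "synthetic_config")
}

flip_pattern <- function(profile, eps) {
  flips <- stats::runif(length(profile)) < eps
  out <- profile
  out[flips] <- 1L - out[flips]
  out
}

#' Generate a synthetic dam-litter culture dataset
#'
#' Draws a latent binary genus profile per family (Bernoulli at the
#' baseline prevalence, shared-core genera forced present) and emits,
#' per subject and time point, a sample whose pattern is the family
#' profile with each genus independently flipped at the time point's
#' flip rate; meconium samples additionally drop each present genus
#' with the meconium-dropout probability. Each presence becomes one
#' isolation record with a uniformly drawn growth class. Output is
#' fully reproducible from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `samples` (metadata frame), `records` (isolation
#'   records frame) and `truth` (family profiles, flip rates, dropout
#'   and seed used).
#' @export
generate_litters <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- length(config$genus_pool)
  fams <- sprintf("F%02d", seq_len(config$n_families))
  sizes <- if (length(config$litter_sizes) == config$n_families) {
    as.integer(config$litter_sizes)
  } else {
    as.integer(sample(config$litter_sizes, config$n_families,
                      replace = TRUE))
  }
  profiles <- matrix(stats::rbinom(g * config$n_families, 1L,
                                   config$baseline_prevalence),
                     nrow = config$n_families,
                     dimnames = list(fams, config$genus_pool))
  profiles[, config$shared_core] <- 1L

  meta <- list(); recs <- list()
  add_sample <- function(fam, subject, role, matrix_type, tp, pattern) {
    sid <- paste(subject, matrix_type, tp, sep = "_")
    meta[[length(meta) + 1L]] <<- data.frame(
      sample_id = sid, family_id = fam, subject_id = subject,
      subject_role = role, matrix = matrix_type, time_point = tp,
      stringsAsFactors = FALSE)
    present <- which(pattern == 1L)
    if (length(present)) {
      recs[[length(recs) + 1L]] <<- data.frame(
        sample_id = sid,
        genus = config$genus_pool[present],
        species = "",
        growth = sample(c("low", "moderate", "high"), length(present),
                        replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  for (fi in seq_along(fams)) {
    fam <- fams[fi]
    prof <- profiles[fi, ]
    dam <- paste0(fam, "-D")
    for (tp in tp_levels()) {
      add_sample(fam, dam, "dam", "rectal", tp,
                 flip_pattern(prof, config$flip_rates[[tp]]))
    }
    if (config$include_dam_matrices) {
      for (tp in c("T0", "T2")) {
        add_sample(fam, dam, "dam", "vaginal", tp,
                   flip_pattern(prof, config$flip_rates[[tp]]))
        add_sample(fam, dam, "dam", "mammary_secretion", tp,
                   flip_pattern(prof, config$flip_rates[[tp]]))
      }
    }
    for (pi in seq_len(sizes[fi])) {
      pup <- sprintf("%s-P%d", fam, pi)
      mec <- flip_pattern(prof, config$flip_rates[["T0"]])
      if (config$meconium_dropout > 0) {
        present <- which(mec == 1L)
        drop <- present[stats::runif(length(present)) <
                          config$meconium_dropout]
        mec[drop] <- 0L
      }
      add_sample(fam, pup, "puppy", "meconium", "T0", mec)
      for (tp in c("T2", "T30", "T60")) {
        add_sample(fam, pup, "puppy", "rectal", tp,
                   flip_pattern(prof, config$flip_rates[[tp]]))
      }
    }
  }
  samples <- do.call(rbind, meta)
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sample_id = character(0), genus = character(0),
               species = character(0), growth = character(0),
               stringsAsFactors = FALSE)
  rownames(samples) <- rownames(records) <- NULL
  validate_sample_meta(samples)
  list(samples = samples, records = records,
       truth = list(profiles = profiles,
                    flip_rates = config$flip_rates,
                    meconium_dropout = config$meconium_dropout,
                    litter_sizes = stats::setNames(sizes, fams),
                    seed = config$seed, preset = config$preset))
}

#' Estimate the per-sample flip rate of a family/time-point cell
#'
#' Inverts the expected pairwise Hamming disagreement of independent
#' per-genus flips: two samples generated from one profile with flip
#' rate eps disagree at a genus with probability 2 eps (1 - eps), so
#' eps-hat = (1 - sqrt(1 - 2 h)) / 2 where h is the mean pairwise
#' Hamming disagreement fraction in the cell. The estimate is clipped
#' to \[0, 0.5\]; disagreement above 0.5 (outside the model) returns
#' 0.5 with a warning.
#'
#' @param m presence matrix.
#' @param samples sample metadata.
#' @param family_id,time_point the cell to estimate.
#' @return estimated flip rate in \[0, 0.5\].
#' @export
estimate_flip_rate <- function(m, samples, family_id, time_point) {
  ids <- samples$sample_id[samples$family_id == family_id &
                             samples$time_point == time_point]
  ids <- intersect(ids, rownames(m))
  if (length(ids) < 2L) {
    stop("need >= 2 samples in the cell to estimate a flip rate",
         call. = FALSE)
  }
  x <- m[ids, , drop = FALSE]
  pairs <- utils::combn(length(ids), 2L)
  ham <- apply(pairs, 2L, function(p) mean(x[p[1], ] != x[p[2], ]))
  hbar <- mean(ham)
  if (hbar > 0.5) {
    warning("mean Hamming disagreement ", signif(hbar, 3),
            " exceeds 0.5; returning 0.5", call. = FALSE)
    return(0.5)
  }
  (1 - sqrt(1 - 2 * hbar)) / 2
}

#' Write a generated dataset to disk
#'
#' Emits the long-format CSV consumed by [read_records()] plus a truth
#' JSON (profiles, flip rates, seed) for parameter-recovery checks.
#'
#' @param sim output of [generate_litters()].
#' @param dir output directory (created if absent).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records_path <- file.path(dir, "records.csv")
  truth_path <- file.path(dir, "truth.json")
  write_records(sim$samples, sim$records, records_path)
  truth <- sim$truth
  truth$profiles <- as.data.frame(truth$profiles)
  truth$flip_rates <- as.list(truth$flip_rates)
  truth$litter_sizes <- as.list(truth$litter_sizes)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(records = records_path, truth = truth_path))
}
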