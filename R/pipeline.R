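#' Run the full convergence analysis pipeline
#'
#' One call from isolation records to every analysis artifact, per
#' matrix filter: binary encoding, phi distance matrix, within-family
#' heterogeneity with exact rank-sum comparisons of every later time
#' point against birth, one complete-linkage dendrogram (Newick) per
#' family, one 2D scaling per family with per-time-point convex-hull
#' areas, and pooled area comparisons (T0 vs T30, T0 vs T60). All
#' stage outputs go to `out_dir` as plain-text files and a JSON report
#' collects every p-value, area and configuration detail.
#'
#' @param input either a path to a long-format records CSV/TSV (see
#'   [read_records()]) or a list with `samples` and `records`.
#' @param out_dir output directory, created if absent.
#' @param filters matrix filters to run (default both `"all"` and
#'   `"rectal_only"`).
#' @param transform,constant_policy passed to [phi_distance_matrix()].
#' @param include_dams include dam samples in family sets (default
#'   `TRUE`).
#' @param holm_adjust add Holm-adjusted p-values to the birth
#'   comparisons (default `FALSE`: raw p, three comparisons).
#' @param genus_universe optional fixed genus universe for the
#'   encoding.
#' @param overwrite allow overwriting a directory that already holds a
#'   report (default `FALSE`).
#' @param verbose emit progress/degeneracy messages (default `TRUE`).
#' @return the report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(input, out_dir,
                         filters = c("all", "rectal_only"),
                         transform = c("half_one_minus_phi",
                                       "one_minus_phi"),
                         constant_policy = c("neutral", "error"),
                         include_dams = TRUE,
                         holm_adjust = FALSE,
                         genus_universe = NULL,
                         overwrite = FALSE,
                         verbose = TRUE) {
  transform <- match.arg(transform)
  constant_policy <- match.arg(constant_policy)
  filters <- match.arg(filters, c("all", "rectal_only"),
                       several.ok = TRUE)
  note <- if (verbose) message else function(...) invisible(NULL)
  quiet <- if (verbose) identity else suppressMessages

  if (is.character(input)) {
    input_path <- input
    parsed <- read_records(input)
  } else {
    stopifnot(is.list(input), all(c("samples", "records") %in% names(input)))
    input_path <- NA_character_
    parsed <- input
  }
  samples <- parsed$samples
  records <- parsed$records

  report_path <- file.path(out_dir, "report.json")
  if (file.exists(report_path) && !overwrite) {
    stop("output directory already holds a report; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  m <- encode_presence(records, samples, genus_universe = genus_universe)
  write_presence_tsv(m, file.path(out_dir, "presence.tsv"))
  note("encoded ", nrow(m), " samples x ", ncol(m), " genera")

  filter_reports <- lapply(filters, function(flt) {
    keep <- samples$matrix %in% resolve_matrix_filter(flt)
    sub_samples <- samples[keep, , drop = FALSE]
    sub_m <- m[sub_samples$sample_id, , drop = FALSE]
    d <- quiet(phi_distance_matrix(sub_m, transform = transform,
                                   constant_policy = constant_policy))
    write_distance_csv(d, file.path(out_dir,
                                    paste0("distance_", flt, ".csv")))

    het <- within_family_heterogeneity(d, sub_samples,
                                       matrix_filter = flt,
                                       include_dams = include_dams)
    utils::write.table(het,
                       file.path(out_dir,
                                 paste0("heterogeneity_", flt, ".csv")),
                       sep = ",", row.names = FALSE, quote = FALSE)
    birth <- compare_to_birth(het, holm_adjust = holm_adjust)

    fams <- sort(unique(sub_samples$family_id))
    area_rows <- list()
    for (fam in fams) {
      ids <- sub_samples$sample_id[sub_samples$family_id == fam]
      if (length(ids) >= 2L) {
        tree <- complete_linkage(d[ids, ids, drop = FALSE])
        writeLines(to_newick(tree),
                   file.path(out_dir, sprintf("dendrogram_%s_%s.nwk",
                                              flt, fam)))
      } else {
        note("family ", fam, ": <2 samples under filter ", flt,
             ", no dendrogram")
      }
      if (length(ids) >= 3L) {
        ord <- classical_mds_2d(d[ids, ids, drop = FALSE])
        coords <- data.frame(sample_id = ord$labels, ord$coords,
                             goodness = ord$goodness, row.names = NULL)
        utils::write.table(coords,
                           file.path(out_dir,
                                     sprintf("coords_%s_%s.csv", flt, fam)),
                           sep = ",", row.names = FALSE, quote = FALSE)
        fam_meta <- sub_samples[sub_samples$family_id == fam, , drop = FALSE]
        area_rows[[fam]] <- quiet(group_areas(ord, fam_meta))
      } else {
        note("family ", fam, ": <3 samples under filter ", flt,
             ", no ordination")
      }
    }
    areas <- if (length(area_rows)) {
      do.call(rbind, c(area_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(family_id = character(0), time_point = character(0),
                 n_points = integer(0), area = numeric(0))
    }
    utils::write.table(areas,
                       file.path(out_dir, paste0("areas_", flt, ".csv")),
                       sep = ",", row.names = FALSE, quote = FALSE)
    area_tests <- compare_areas_to_birth(areas)

    list(matrix_filter = flt,
         n_samples = nrow(sub_samples),
         constant_rows = attr(d, "constant_rows"),
         heterogeneity = het,
         birth_comparisons = birth,
         areas = areas,
         area_comparisons = area_tests)
  })
  names(filter_reports) <- filters

  report <- list(
    package = "litterflora",
    version = as.character(utils::packageVersion("litterflora")),
    config = list(input = input_path, filters = filters,
                  transform = transform,
                  constant_policy = constant_policy,
                  include_dams = include_dams,
                  holm_adjust = holm_adjust),
    input_checksum = unname(tools::md5sum(file.path(out_dir,
                                                    "presence.tsv"))),
    n_samples = nrow(samples),
    n_genera = ncol(m),
    filters = filter_reports,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  note("report written to ", report_path)
  invisible(report)
}

#' Compare per-family polygon areas at T30/T60 against birth
#'
#' Pools each family's convex-hull area per time point and runs the
#' exact Wilcoxon rank-sum test of T30 and of T60 areas against the
#' T0 areas.
#'
#' @param areas an area table as produced by [group_areas()] (rows
#'   from several families may be concatenated).
#' @param times time points compared against T0 (default T30 and T60).
#' @return data.frame with one row per comparison (same layout as
#'   [compare_to_birth()]).
#' @export
compare_areas_to_birth <- function(areas, times = c("T30", "T60")) {
  stopifnot(all(c("time_point", "area") %in% names(areas)))
  pick <- function(tp) areas$area[areas$time_point == tp]
  b0 <- pick("T0")
  rows <- lapply(times, function(tp) {
    v <- pick(tp)
    if (length(v) < 2L || length(b0) < 2L) {
      return(data.frame(comparison = paste0(tp, "_vs_T0"),
                        time_point = tp, W = NA_real_,
                        n_a = length(v), n_b = length(b0),
                        p = NA_real_, method = "not_testable",
                        stringsAsFactors = FALSE))
    }
    rs <- ranksum_exact(v, b0)
    data.frame(comparison = paste0(tp, "_vs_T0"), time_point = tp,
               W = rs$statistic_W, n_a = rs$n_a, n_b = rs$n_b,
               p = rs$p_two_sided, method = rs$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
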