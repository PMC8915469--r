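#' litterflora: culture-based dam-litter microbiota convergence analysis
#'
#' Tools to analyse culture-based bacterial isolation records from
#' dam-litter units ("families": a mother plus her litter) sampled at
#' birth (T0) and days 2, 30 and 60 post-partum (T2, T30, T60). Samples
#' are encoded as binary genus presence/absence patterns, compared with
#' the phi association coefficient, and summarised as within-family
#' heterogeneity trajectories, per-family complete-linkage dendrograms
#' and two-dimensional scaling ordinations with per-time-point
#' convex-hull areas. Exact Wilcoxon rank-sum tests compare every later
#' time point against birth.
#'
#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for sample metadata and growth classes.
tp_levels <- function() c("T0", "T2", "T30", "T60")
matrix_levels <- function() c("rectal", "meconium", "vaginal", "mammary_secretion")
role_levels <- function() c("dam", "puppy")
growth_levels <- function() c("no_growth", "low", "moderate", "high")

#' Classify colony counts into growth classes
#'
#' Maps colony-forming-unit counts (per 10 uL of suspension plated at
#' first isolation) onto the ordinal growth scale used for culture
#' records: 0 is `no_growth`, 1-10 `low`, 11-30 `moderate`, 31 or more
#' `high`.
#'
#' @param cfu_count vector of non-negative integer colony counts.
#' @return character vector of growth classes, same length as input.
#' @examples
#' classify_growth(c(0, 5, 30, 31))
#' @export
classify_growth <- function(cfu_count) {
  if (length(cfu_count) == 0L) return(character(0))
  if (!is.numeric(cfu_count) || anyNA(cfu_count)) {
    stop("cfu_count must be numeric with no missing values", call. = FALSE)
  }
  if (any(cfu_count < 0) || any(cfu_count != trunc(cfu_count))) {
    stop("cfu_count must contain non-negative integers", call. = FALSE)
  }
  out <- character(length(cfu_count))
  out[cfu_count == 0] <- "no_growth"
  out[cfu_count >= 1 & cfu_count <= 10] <- "low"
  out[cfu_count >= 11 & cfu_count <= 30] <- "moderate"
  out[cfu_count >= 31] <- "high"
  out
}

#' Canonicalize genus names
#'
#' Trims and collapses whitespace, applies an optional synonym map
#' (matched case-insensitively on the trimmed string, so e.g.
#' `"E. coli"` can be mapped to `"Escherichia"`), strips a trailing
#' `"spp."`/`"sp."` qualifier and capitalizes the genus name.
#'
#' @param genus character vector of raw genus labels.
#' @param synonyms optional named character vector: names are raw
#'   labels, values the canonical genus.
#' @return character vector of canonical genus names.
#' @examples
#' canonicalize_genus(c(" clostridium spp. ", "E. coli"),
#'                    synonyms = c("E. coli" = "Escherichia"))
#' @export
canonicalize_genus <- function(genus, synonyms = NULL) {
  g <- gsub("\\s+", " ", trimws(as.character(genus)))
  if (!is.null(synonyms)) {
    if (is.null(names(synonyms))) {
      stop("synonyms must be a named character vector", call. = FALSE)
    }
    key <- tolower(gsub("\\s+", " ", trimws(names(synonyms))))
    hit <- match(tolower(g), key)
    g[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  g <- sub("\\s+spp?\\.?$", "", g, ignore.case = TRUE)
  has <- nzchar(g)
  g[has] <- paste0(toupper(substring(g[has], 1L, 1L)),
                   tolower(substring(g[has], 2L)))
  g
}

validate_sample_meta <- function(samples) {
  req <- c("sample_id", "family_id", "subject_id", "subject_role",
           "matrix", "time_point")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample metadata is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  chk_enum <- function(values, levels, what) {
    bad <- which(!values %in% levels)
    if (length(bad)) {
      stop(sprintf("unknown %s label '%s' (sample %s)", what,
                   values[bad[1L]], samples$sample_id[bad[1L]]),
           call. = FALSE)
    }
  }
  chk_enum(samples$subject_role, role_levels(), "subject_role")
  chk_enum(samples$matrix, matrix_levels(), "matrix")
  chk_enum(samples$time_point, tp_levels(), "time_point")
  bad <- samples$matrix == "meconium" &
    !(samples$subject_role == "puppy" & samples$time_point == "T0")
  if (any(bad)) {
    stop("meconium is only valid for puppies at T0 (sample ",
         samples$sample_id[which(bad)[1L]], ")", call. = FALSE)
  }
  bad <- samples$matrix %in% c("vaginal", "mammary_secretion") &
    !(samples$subject_role == "dam" & samples$time_point %in% c("T0", "T2"))
  if (any(bad)) {
    stop("vaginal/mammary_secretion are only valid for dams at T0/T2 ",
         "(sample ", samples$sample_id[which(bad)[1L]], ")", call. = FALSE)
  }
  invisible(samples)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

#' Read isolation records and sample metadata from a long-format table
#'
#' Reads a CSV/TSV with one row per (sample, genus) isolation plus the
#' sample metadata columns, validates all controlled vocabularies, and
#' splits the table into a per-sample metadata frame and an isolation
#' record frame. Sterile (no-growth) samples are represented by a
#' metadata-only row with an empty genus and yield no record.
#'
#' Required columns: `sample_id`, `family_id`, `subject_id`,
#' `subject_role`, `matrix`, `time_point`, `genus`. Optional: `species`,
#' `growth` (blank growth becomes `"unclassified"`).
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs comma vs tab.
#' @param synonyms optional genus synonym map, see
#'   [canonicalize_genus()].
#' @return list with elements `samples` (one row per sample) and
#'   `records` (one row per isolation).
#' @seealso [write_records()], [encode_presence()]
#' @export
read_records <- function(path, sep = NULL, synonyms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           na.strings = character(0),
                           check.names = FALSE, strip.white = TRUE)
  parse_records(raw, synonyms = synonyms)
}

#' @rdname read_records
#' @param table a data.frame already in the long format above (used by
#'   the synthetic generator and tests to bypass file I/O).
#' @export
parse_records <- function(table, synonyms = NULL) {
  req <- c("sample_id", "family_id", "subject_id", "subject_role",
           "matrix", "time_point", "genus")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  n <- nrow(tab)
  meta_cols <- req[1:6]
  chk_enum <- function(values, levels, what) {
    bad <- which(!values %in% levels)
    if (length(bad)) {
      stop(sprintf("row %d: unknown %s label '%s'", bad[1L], what,
                   values[bad[1L]]), call. = FALSE)
    }
  }
  chk_enum(tab$subject_role, role_levels(), "subject_role")
  chk_enum(tab$matrix, matrix_levels(), "matrix")
  chk_enum(tab$time_point, tp_levels(), "time_point")

  meta <- unique(tab[meta_cols])
  if (anyDuplicated(meta$sample_id)) {
    dup <- meta$sample_id[duplicated(meta$sample_id)][1L]
    rows <- which(tab$sample_id == dup)
    stop(sprintf("sample_id '%s' has conflicting metadata (rows %s)",
                 dup, paste(rows, collapse = ", ")), call. = FALSE)
  }
  rownames(meta) <- NULL
  validate_sample_meta(meta)

  genus <- canonicalize_genus(tab$genus, synonyms = synonyms)
  has_rec <- nzchar(genus) & !is.na(genus)
  growth <- if ("growth" %in% names(tab)) tolower(tab$growth) else
    rep("", n)
  growth[!nzchar(growth) | is.na(growth)] <- "unclassified"
  bad <- which(has_rec & !growth %in% c(growth_levels(), "unclassified"))
  if (length(bad)) {
    stop(sprintf("row %d: unknown growth label '%s'", bad[1L],
                 growth[bad[1L]]), call. = FALSE)
  }
  species <- if ("species" %in% names(tab)) tab$species else rep("", n)
  species[is.na(species)] <- ""
  records <- data.frame(
    sample_id = tab$sample_id[has_rec],
    genus = genus[has_rec],
    species = species[has_rec],
    growth = growth[has_rec],
    row = which(has_rec),
    stringsAsFactors = FALSE
  )
  list(samples = meta, records = records)
}

#' Write records back to the long-format CSV
#'
#' Inverse of [read_records()]: emits one row per isolation record and
#' one metadata-only row (blank genus) per sample with no isolations,
#' so a read/write round trip preserves the presence matrix exactly.
#'
#' @param samples,records as returned by [read_records()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_records <- function(samples, records, path, sep = ",") {
  validate_sample_meta(samples)
  long <- merge(records[c("sample_id", "genus", "species", "growth")],
                samples, by = "sample_id")
  sterile <- setdiff(samples$sample_id, records$sample_id)
  if (length(sterile)) {
    extra <- samples[samples$sample_id %in% sterile, , drop = FALSE]
    extra$genus <- ""
    extra$species <- ""
    extra$growth <- ""
    long <- rbind(long, extra[names(long)])
  }
  long <- long[order(long$sample_id, long$genus), ]
  cols <- c("sample_id", "family_id", "subject_id", "subject_role",
            "matrix", "time_point", "genus", "species", "growth")
  utils::write.table(long[cols], path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Encode isolation records as a binary presence matrix
#'
#' Builds the samples x genera 0/1 pattern matrix ("codified 1/0
#' patterns"): a cell is 1 when at least one isolation record links the
#' sample to the genus, regardless of species or growth class. Samples
#' with no records get all-zero rows. The genus universe defaults to
#' the sorted union of genera observed across the whole dataset so that
#' patterns are comparable across families; a fixed universe may be
#' supplied for cross-dataset comparability.
#'
#' @param records,samples as returned by [read_records()].
#' @param genus_universe optional character vector of genus columns;
#'   must contain every observed genus.
#' @return integer matrix with sample ids as row names and genera as
#'   column names.
#' @export
encode_presence <- function(records, samples, genus_universe = NULL) {
  validate_sample_meta(samples)
  orphan <- setdiff(records$sample_id, samples$sample_id)
  if (length(orphan)) {
    stop("record(s) reference unknown sample_id(s): ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  observed <- sort(unique(records$genus))
  if (is.null(genus_universe)) {
    genus_universe <- observed
  } else {
    genus_universe <- as.character(genus_universe)
    if (anyDuplicated(genus_universe)) {
      stop("genus_universe contains duplicates", call. = FALSE)
    }
    miss <- setdiff(observed, genus_universe)
    if (length(miss)) {
      stop("genus_universe is missing observed genera: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  m <- matrix(0L, nrow = nrow(samples), ncol = length(genus_universe),
              dimnames = list(samples$sample_id, genus_universe))
  if (nrow(records)) {
    m[cbind(match(records$sample_id, samples$sample_id),
            match(records$genus, genus_universe))] <- 1L
  }
  m
}

#' Isolation frequency of each genus in a sample group
#'
#' Counts, for each genus of the presence matrix, how many samples of a
#' selected group are positive, and the percentage over the group size
#' (reported to one decimal).
#'
#' @param m presence matrix from [encode_presence()].
#' @param samples sample metadata (needed when `group` is a predicate).
#' @param group either `NULL` (all samples), a character vector of
#'   sample ids, or a predicate function taking the metadata frame and
#'   returning a logical vector.
#' @return data.frame with columns `genus`, `count`, `percent`, sorted
#'   by decreasing count.
#' @examples
#' \dontrun{
#' isolation_frequency(m, samples,
#'   group = function(s) s$matrix == "meconium")
#' }
#' @export
isolation_frequency <- function(m, samples = NULL, group = NULL) {
  ids <- rownames(m)
  if (is.null(group)) {
    sel <- ids
  } else if (is.function(group)) {
    if (is.null(samples)) {
      stop("samples metadata required for a predicate group", call. = FALSE)
    }
    keep <- group(samples)
    sel <- intersect(samples$sample_id[keep], ids)
  } else {
    sel <- intersect(as.character(group), ids)
  }
  if (length(sel) == 0L) {
    stop("group selects no samples", call. = FALSE)
  }
  counts <- colSums(m[sel, , drop = FALSE])
  out <- data.frame(genus = colnames(m),
                    count = as.integer(counts),
                    percent = round(100 * counts / length(sel), 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$count, out$genus), , drop = FALSE]
}

#' Write / read a presence matrix as TSV
#'
#' First column `sample_id`, remaining columns one per genus, cells 0/1.
#'
#' @param m presence matrix.
#' @param path file path.
#' @return `path` invisibly (write) or an integer matrix (read).
#' @export
write_presence_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}
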