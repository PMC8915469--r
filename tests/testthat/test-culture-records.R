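test_that("CFU counts map onto the growth classes at the stated boundaries", {
  expect_equal(classify_growth(c(0, 1, 5, 10, 11, 30, 31, 200)),
               c("no_growth", "low", "low", "low", "moderate", "moderate",
                 "high", "high"))
  expect_error(classify_growth(-1), "non-negative")
  expect_error(classify_growth(2.5), "non-negative integers")
  expect_error(classify_growth(NA_real_), "missing")
})

test_that("genus names are canonicalized and synonym-mapped", {
  expect_equal(canonicalize_genus("  clostridium   spp. "), "Clostridium")
  expect_equal(canonicalize_genus("PROTEUS sp"), "Proteus")
  expect_equal(canonicalize_genus("E. coli",
                                  synonyms = c("e. coli" = "Escherichia")),
               "Escherichia")
  expect_equal(canonicalize_genus("Staphylococcus"), "Staphylococcus")
})

test_that("long-format tables parse into metadata plus records", {
  tab <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    family_id = "F01", subject_id = c("P1", "P1", "P2"),
    subject_role = "puppy", matrix = "rectal",
    time_point = "T2",
    genus = c("Escherichia", "Proteus", ""),
    stringsAsFactors = FALSE
  )
  parsed <- parse_records(tab)
  expect_equal(nrow(parsed$samples), 2L)
  expect_equal(nrow(parsed$records), 2L)
  expect_equal(parsed$records$growth, rep("unclassified", 2))

  bad_tp <- tab
  bad_tp$time_point <- c("T2", "T2", "T15")
  expect_error(parse_records(bad_tp), "row 3.*time_point")

  conflict <- tab
  conflict$subject_id <- c("P1", "P9", "P2")
  expect_error(parse_records(conflict), "conflicting metadata")
})

test_that("metadata invariants on matrix type, role and time are enforced", {
  no_records <- data.frame(sample_id = character(0), genus = character(0))
  s <- data.frame(sample_id = "x", family_id = "F", subject_id = "D",
                  subject_role = "dam", matrix = "meconium",
                  time_point = "T0", stringsAsFactors = FALSE)
  expect_error(encode_presence(no_records, s), "meconium")
  s$subject_role <- "puppy"; s$matrix <- "vaginal"
  expect_error(encode_presence(no_records, s), "vaginal")
})

test_that("presence encoding matches the stated cell semantics", {
  samples <- data.frame(sample_id = c("s1", "s2"), family_id = "F01",
                        subject_id = c("P1", "P2"), subject_role = "puppy",
                        matrix = "rectal", time_point = "T2",
                        stringsAsFactors = FALSE)
  records <- data.frame(
    sample_id = c("s1", "s1", "s1"),
    genus = c("Escherichia", "Proteus", "Escherichia"),
    species = c("coli", "mirabilis", "fergusonii"), growth = "low",
    stringsAsFactors = FALSE)
  m <- encode_presence(records, samples,
                       genus_universe = c("Clostridium", "Escherichia",
                                          "Proteus"))
  expect_equal(unname(m["s1", ]), c(0L, 1L, 1L))   # two species, one cell
  expect_equal(unname(m["s2", ]), c(0L, 0L, 0L))   # sterile sample row
  expect_true(all(m %in% 0:1))

  # order independence
  m2 <- encode_presence(records[c(3, 1, 2), ], samples,
                        genus_universe = c("Clostridium", "Escherichia",
                                           "Proteus"))
  expect_identical(m, m2)

  orphan <- rbind(records,
                  data.frame(sample_id = "ghost", genus = "Proteus",
                             species = "", growth = "low"))
  expect_error(encode_presence(orphan, samples), "ghost")
  expect_error(encode_presence(records, samples,
                               genus_universe = c("Escherichia")),
               "missing observed genera")
})

test_that("isolation frequencies count positives with one-decimal percents", {
  set.seed(7)
  samples <- data.frame(
    sample_id = sprintf("c%d", 1:6), family_id = "F01",
    subject_id = sprintf("D%d", 1:6), subject_role = "dam",
    matrix = "mammary_secretion", time_point = "T0",
    stringsAsFactors = FALSE)
  records <- data.frame(sample_id = c("c1", "c2", "c3"),
                        genus = "Escherichia", species = "", growth = "low",
                        stringsAsFactors = FALSE)
  m <- encode_presence(records, samples,
                       genus_universe = c("Escherichia", "Proteus"))
  freq <- isolation_frequency(m, samples)
  expect_equal(freq$count[freq$genus == "Escherichia"], 3L)
  expect_equal(freq$percent[freq$genus == "Escherichia"], 50.0)
  expect_equal(freq$count[freq$genus == "Proteus"], 0L)
  expect_equal(freq$percent[freq$genus == "Proteus"], 0.0)
  expect_error(isolation_frequency(m, samples, group = character(0)),
               "no samples")

  # column sums equal the all-sample frequency counts
  big <- rand_binary_matrix(20, 8)
  samples_big <- data.frame(sample_id = rownames(big), family_id = "F01",
                            subject_id = rownames(big),
                            subject_role = "puppy", matrix = "rectal",
                            time_point = "T30", stringsAsFactors = FALSE)
  f <- isolation_frequency(big, samples_big)
  expect_equal(f$count[match(colnames(big), f$genus)],
               unname(colSums(big)))
})

test_that("records and presence matrices survive file round trips", {
  toy <- toy_dataset()
  m0 <- encode_presence(toy$records, toy$samples)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_records(toy$samples, toy$records, csv)
  back <- read_records(csv)
  m1 <- encode_presence(back$records, back$samples)
  expect_identical(m0[rownames(m1), colnames(m1)], m1)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_presence_tsv(m0, tsv)
  expect_identical(read_presence_tsv(tsv), m0)
})
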