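# small hand-built fixture: 2 chemicals x assays over 5 proteins
toy_toxcast <- function() {
  ann <- data.frame(
    assay_id = c("NVS_rec_R1",                       # NVS receptor
                 "ATG_rec_R2",                       # non-NVS receptor
                 "ATG_TF1_up", "ATG_TF1_dn",         # TF up/down pair
                 "ATG_TF2_up", "ATG_TF2_dn", "TOX_TF2",  # pair + 3rd assay
                 "NVS_rec_NR1",                      # nuclear receptor family
                 "TOX_K1", "ACEA_K1",                # two assays, one protein
                 "BSK_bg_1"),                        # unmapped filler
    protein_id = c("R1", "R2", "TF1", "TF1", "TF2", "TF2", "TF2",
                   "NR1", "K1", "K1", ""),
    target_type_sub = c("receptor", "receptor", rep("transcription factor", 4),
                        "transcription factor", "receptor",
                        "enzyme", "enzyme", "cell-based"),
    target_family = c("gpcr", "gpcr", rep("dna binding", 5),
                      "nuclear receptor", "kinase", "kinase", "background"),
    vendor = c("NVS", "ATG", rep("ATG", 5), "NVS", "TOX21", "ACEA", "BSK"))
  ann <- annotate_assay_directions(ann)
  hits <- matrix(NA_real_, 2, nrow(ann),
                 dimnames = list(c("chemA", "chemB"), ann$assay_id))
  hits["chemA", ] <- c(1, 1, 1, 0, 1, 0, 1, 1, 1, 0, 0)
  hits["chemB", ] <- c(0, NA, 0, 0, NA, NA, NA, -1, -1, NA, 0)
  list(ann = ann, hits = hits)
}

test_that("responsiveness calls follow the all-1 rule with pair collapse", {
  tt <- toy_toxcast()
  calls <- call_responsive(tt$hits, tt$ann, "chemA")
  expect_equal(calls[["R1"]], "responsive")       # single assay = 1
  expect_equal(calls[["TF1"]], "responsive")      # up/dn pair {1,0} -> 1
  expect_equal(calls[["TF2"]], "responsive")      # pair {1,0} + third = 1
  expect_equal(calls[["K1"]], "nonresponsive")    # {1, 0}, not a pair
  callsB <- call_responsive(tt$hits, tt$ann, "chemB")
  expect_equal(callsB[["R1"]], "nonresponsive")
  expect_equal(callsB[["NR1"]], "undetermined")   # only -1
  expect_equal(callsB[["K1"]], "undetermined")    # {-1, NA}
  expect_error(call_responsive(tt$hits, tt$ann, "nope"), "chemical")
  # calls are invariant to assay column order
  perm <- sample(ncol(tt$hits))
  expect_equal(call_responsive(tt$hits[, perm], tt$ann, "chemA"), calls)
})

test_that("source/target classification applies NVS and family rules", {
  tt <- toy_toxcast()
  calls <- call_responsive(tt$hits, tt$ann, "chemA")
  st <- classify_sources_targets(tt$ann, names(calls)[calls == "responsive"])
  expect_setequal(st$sources, "R1")       # R2 responsive but non-NVS;
                                          # NR1 responsive but nuclear receptor
  expect_setequal(st$targets, c("TF1", "TF2"))
  empty <- classify_sources_targets(tt$ann, character(0))
  expect_length(empty$sources, 0)
  expect_length(empty$targets, 0)
})

test_that("dual receptor/TF proteins follow the conflict policy", {
  ann <- annotate_assay_directions(data.frame(
    assay_id = c("NVS_rec_X", "ATG_X_up"),
    protein_id = "X",
    target_type_sub = c("receptor", "transcription factor"),
    target_family = "gpcr", vendor = c("NVS", "ATG")))
  expect_message(st <- classify_sources_targets(ann, "X"), "both")
  expect_length(st$sources, 0)
  expect_length(st$targets, 0)
  suppressMessages({
    st_r <- classify_sources_targets(ann, "X", conflict = "receptor")
    st_t <- classify_sources_targets(ann, "X", conflict = "tf")
  })
  expect_equal(st_r$sources, "X")
  expect_equal(st_t$targets, "X")
})

test_that("chemical selection needs >= min_tested assays plus S and T", {
  tt <- toy_toxcast()
  # chemA: 11 tested values... count: 1,1,1,0,1,0,1,1,1,0,0 = 11 tested
  expect_setequal(select_chemicals(tt$hits, tt$ann, min_tested = 11), "chemA")
  expect_length(select_chemicals(tt$hits, tt$ann, min_tested = 12), 0)
  # chemB is tested enough at low thresholds but has no responsive S/T
  expect_setequal(select_chemicals(tt$hits, tt$ann, min_tested = 3), "chemA")
  # boundary at the default threshold of 500 successfully tested assays
  filler <- sprintf("BSK_f_%03d", 1:500)
  ann <- annotate_assay_directions(rbind(
    tt$ann[, c("assay_id", "protein_id", "target_type_sub",
               "target_family", "vendor")],
    data.frame(assay_id = filler, protein_id = "",
               target_type_sub = "cell-based", target_family = "background",
               vendor = "BSK")))
  hits <- cbind(tt$hits,
                matrix(0, 2, 500, dimnames = list(NULL, filler)))
  hits["chemA", filler[1:12]] <- NA   # chemA: 499 tested -> excluded
  expect_length(select_chemicals(hits, ann), 0)
  hits["chemA", filler[1]] <- 0       # exactly 500 tested -> included
  expect_setequal(select_chemicals(hits, ann), "chemA")
})

test_that("z-score aggregation takes the per-protein maximum", {
  tt <- toy_toxcast()
  zs <- tt$hits; zs[] <- NA_real_
  zs["chemA", "NVS_rec_R1"] <- 2.3
  zs["chemA", "ATG_TF1_up"] <- 1.0
  zs["chemA", "ATG_TF1_dn"] <- 3.5
  z <- aggregate_zscore(zs, tt$ann, "chemA")
  expect_equal(z[["R1"]], 2.3)
  expect_equal(z[["TF1"]], 3.5)
  expect_false("TF2" %in% names(z))   # all z missing -> omitted
})

test_that("toxicant profiles assemble roles and survive a file round-trip", {
  tt <- toy_toxcast()
  zs <- tt$hits; zs[] <- NA_real_
  zs["chemA", "NVS_rec_R1"] <- 1.7
  pr <- toxicant_profile(tt$hits, tt$ann, "chemA", zmatrix = zs)
  expect_s3_class(pr, "toxicant_profile")
  expect_setequal(pr$sources, "R1")
  expect_setequal(pr$targets, c("TF1", "TF2"))
  expect_length(intersect(pr$sources, pr$targets), 0)
  expect_setequal(pr$responsive_intermediates, c("R2", "NR1"))
  expect_true("K1" %in% pr$nonresponsive)
  path <- tempfile(fileext = ".tsv")
  write_profile(pr, path)
  pr2 <- read_profile(path, chemical = "chemA")
  expect_setequal(pr2$sources, pr$sources)
  expect_setequal(pr2$targets, pr$targets)
  expect_setequal(pr2$responsive_intermediates, pr$responsive_intermediates)
  expect_equal(pr2$zscores[["R1"]], 1.7)
})
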