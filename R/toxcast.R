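#' Read a ToxCast-style hit matrix
#'
#' The hit matrix is a CSV with chemicals as rows (first column = chemical
#' ID) and assay IDs as columns. Each cell holds one of four values:
#' `1` (hit: AC50 <= 50 uM), `0` (nonhit), `-1` (activity could not be
#' determined) or `NA` (not tested).
#'
#' @param path CSV file path.
#' @return A numeric matrix (chemicals x assays) with row/column names.
#' @export
read_hit_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_hit_matrix(m)
}

#' @rdname read_hit_matrix
#' @param hits a chemicals x assays matrix to validate in place.
#' @export
validate_hit_matrix <- function(hits) {
  vals <- hits[!is.na(hits)]
  if (any(!vals %in% c(1, 0, -1)))
    stop("hit matrix values must be 1, 0, -1 or NA")
  hits
}

#' Read a ToxCast-style z-score matrix
#'
#' Same layout as the hit matrix; cells hold the z-score measuring the
#' severity of the chemical's effect on the assay, or `NA`.
#'
#' @param path CSV file path.
#' @return A numeric matrix aligned with the hit matrix.
#' @export
read_zscore_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' Read an assay annotation table
#'
#' TSV with columns `assay_id`, `protein_id` (UniProtKB accession or empty
#' when the assay maps to no single human protein), `target_type_sub` (the
#' `intended_target_type_sub` classification, e.g. "receptor" or
#' "transcription factor"), `target_family` (the `intended_target_family`,
#' e.g. "nuclear receptor") and `vendor` (assay source prefix, e.g. "NVS").
#'
#' A `direction` column (`up`/`down`/`none`) is derived from the assay ID
#' suffix (`_up`/`_dn` by default) together with the shared `stem`; assays
#' sharing a stem with opposite directions form an up/down pair that is
#' collapsed into a single logical assay during responsiveness calls.
#'
#' @param path TSV file path.
#' @param pair_suffixes length-2 character vector of up/down assay ID
#'   suffixes.
#' @return A data.frame of annotations with derived `direction` and `stem`.
#' @export
read_assay_annotation <- function(path, pair_suffixes = c("_up", "_dn")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "protein_id", "target_type_sub", "target_family",
            "vendor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("assay annotation is missing column(s): ", paste(miss, collapse = ", "))
  annotate_assay_directions(df, pair_suffixes)
}

#' @rdname read_assay_annotation
#' @param annot an annotation data.frame (as documented above) to annotate
#'   in place.
#' @export
annotate_assay_directions <- function(annot, pair_suffixes = c("_up", "_dn")) {
  id <- annot$assay_id
  up <- endsWith(id, pair_suffixes[1L])
  dn <- endsWith(id, pair_suffixes[2L])
  annot$direction <- ifelse(up, "up", ifelse(dn, "down", "none"))
  annot$stem <- id
  annot$stem[up] <- substr(id[up], 1L, nchar(id[up]) - nchar(pair_suffixes[1L]))
  annot$stem[dn] <- substr(id[dn], 1L, nchar(id[dn]) - nchar(pair_suffixes[2L]))
  annot
}

.assays_for_chemical <- function(hits, annot, chemical) {
  if (!chemical %in% rownames(hits))
    stop("chemical not in the hit matrix: ", chemical)
  extra <- setdiff(colnames(hits), annot$assay_id)
  if (length(extra))
    stop("assay(s) missing from the annotation: ",
         paste(utils::head(extra, 5), collapse = ", "))
  hits[chemical, , drop = TRUE]
}

#' Call per-protein responsiveness for one chemical
#'
#' A protein is responsive to a chemical iff every assay mapped to it has
#' value 1 in the hit matrix, where each up/down assay pair first collapses
#' to a single logical assay that is 1 if either member is 1 (0 if either
#' member was tested, otherwise untested). A protein is nonresponsive iff
#' at least one of its assays was successfully tested (0 or 1) but not all
#' collapsed values equal 1, and undetermined iff every value is -1 or NA.
#'
#' @param hits hit matrix (see [read_hit_matrix()]).
#' @param annot assay annotation with derived directions (see
#'   [read_assay_annotation()]).
#' @param chemical a chemical ID (row of `hits`).
#' @return A named character vector over proteins with values
#'   `"responsive"`, `"nonresponsive"` or `"undetermined"`.
#' @export
call_responsive <- function(hits, annot, chemical) {
  vals <- .assays_for_chemical(hits, annot, chemical)
  an <- annot[!is.na(annot$protein_id) & nzchar(annot$protein_id) &
                annot$assay_id %in% names(vals), , drop = FALSE]
  if (nrow(an) == 0L) return(stats::setNames(character(0), character(0)))
  collapse_pair <- function(v) {
    # one logical assay from an up/down pair (or a singleton)
    if (any(v == 1, na.rm = TRUE)) return(1)
    if (any(v == 0, na.rm = TRUE)) return(0)
    if (any(v == -1, na.rm = TRUE)) return(-1)
    NA_real_
  }
  out <- vapply(split(an, an$protein_id), function(a) {
    collapsed <- vapply(split(vals[a$assay_id], a$stem), collapse_pair, 0)
    tested <- collapsed %in% c(0, 1)
    if (!any(tested)) return("undetermined")
    if (all(!is.na(collapsed) & collapsed == 1)) "responsive" else "nonresponsive"
  }, "")
  out
}

#' Classify responsive proteins into receptors (sources) and TFs (targets)
#'
#' A responsive protein enters S_x (sources) iff at least one of its
#' assays is a receptor assay (`target_type_sub` contains "receptor") made
#' by the Novascreen vendor (prefix `NVS`, which tests direct
#' receptor-chemical interaction) whose `target_family` is not "nuclear
#' receptor". It enters T_x (targets) iff at least one of its assays is a
#' transcription-factor assay under the same nuclear-receptor family
#' exclusion. A protein qualifying as both is handled by `conflict`
#' (default: excluded from both sets, with a message), keeping
#' S_x and T_x disjoint.
#'
#' @param annot assay annotation (see [read_assay_annotation()]).
#' @param responsive character vector of responsive protein IDs (e.g. from
#'   [call_responsive()]).
#' @param conflict policy for dual receptor/TF proteins: `"exclude"`
#'   (default), `"receptor"` or `"tf"`.
#' @param receptor_vendor vendor prefix required for receptor assays
#'   (default `"NVS"`).
#' @return A list with character vectors `sources` and `targets`.
#' @export
classify_sources_targets <- function(annot, responsive,
                                     conflict = c("exclude", "receptor", "tf"),
                                     receptor_vendor = "NVS") {
  conflict <- match.arg(conflict)
  an <- annot[!is.na(annot$protein_id) & nzchar(annot$protein_id), , drop = FALSE]
  an <- an[an$protein_id %in% responsive, , drop = FALSE]
  fam_ok <- tolower(an$target_family) != "nuclear receptor"
  type <- tolower(an$target_type_sub)
  is_rec <- grepl("receptor", type, fixed = TRUE) & fam_ok &
    startsWith(toupper(an$vendor), toupper(receptor_vendor))
  is_tf <- grepl("transcription factor", type, fixed = TRUE) & fam_ok
  sources <- unique(an$protein_id[is_rec])
  targets <- unique(an$protein_id[is_tf])
  both <- intersect(sources, targets)
  if (length(both)) {
    message("protein(s) classified both receptor and TF (policy '",
            conflict, "'): ", paste(both, collapse = ", "))
    if (conflict == "exclude") {
      sources <- setdiff(sources, both); targets <- setdiff(targets, both)
    } else if (conflict == "receptor") {
      targets <- setdiff(targets, both)
    } else {
      sources <- setdiff(sources, both)
    }
  }
  list(sources = sources, targets = targets)
}

#' Select chemicals eligible for network reconstruction
#'
#' Keeps chemicals successfully tested (value 0 or 1; -1 and NA both count
#' as not successfully tested) in at least `min_tested` assays that also
#' have at least one responsive receptor and one responsive TF (per
#' [call_responsive()] and [classify_sources_targets()]).
#'
#' @inheritParams call_responsive
#' @param min_tested minimum number of successfully tested assays
#'   (default 500).
#' @param ... passed to [classify_sources_targets()].
#' @return Character vector of eligible chemical IDs (possibly empty).
#' @export
select_chemicals <- function(hits, annot, min_tested = 500, ...) {
  n_tested <- rowSums(matrix(hits %in% c(0, 1), nrow = nrow(hits)))
  cands <- rownames(hits)[n_tested >= min_tested]
  keep <- vapply(cands, function(chem) {
    calls <- call_responsive(hits, annot, chem)
    st <- classify_sources_targets(annot, names(calls)[calls == "responsive"],
                                   ...)
    length(st$sources) >= 1L && length(st$targets) >= 1L
  }, NA)
  cands[keep]
}

#' Aggregate assay z-scores per protein
#'
#' When several assays test the same protein, the protein's z-score for a
#' chemical is the maximum of the corresponding assay z-scores. Proteins
#' with no z-score data are omitted.
#'
#' @param zmatrix z-score matrix aligned with the hit matrix.
#' @param annot assay annotation.
#' @param chemical chemical ID.
#' @return Named numeric vector of per-protein z-scores.
#' @export
aggregate_zscore <- function(zmatrix, annot, chemical) {
  if (!chemical %in% rownames(zmatrix))
    stop("chemical not in the z-score matrix: ", chemical)
  zs <- zmatrix[chemical, , drop = TRUE]
  an <- annot[!is.na(annot$protein_id) & nzchar(annot$protein_id) &
                annot$assay_id %in% names(zs), , drop = FALSE]
  out <- vapply(split(an$assay_id, an$protein_id), function(a) {
    v <- zs[a]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, 0)
  out[!is.na(out)]
}

#' Build a toxicant profile for one chemical
#'
#' Combines responsiveness calls, source/target classification and z-score
#' aggregation into the per-chemical profile consumed by [edgelinker()]:
#' the responsive receptors S_x, responsive TFs T_x, responsive
#' intermediate proteins (responsive but neither source nor target),
#' nonresponsive proteins and per-protein z-scores. When `graph` is given,
#' sources and targets are restricted to interactome members.
#'
#' @inheritParams call_responsive
#' @param zmatrix optional z-score matrix.
#' @param graph optional [interactome] to filter sources/targets against.
#' @param ... passed to [classify_sources_targets()].
#' @return An object of class `toxicant_profile` with elements `chemical`,
#'   `sources`, `targets`, `responsive` (all responsive proteins),
#'   `responsive_intermediates`, `nonresponsive` and `zscores`.
#' @export
toxicant_profile <- function(hits, annot, chemical, zmatrix = NULL,
                             graph = NULL, ...) {
  calls <- call_responsive(hits, annot, chemical)
  responsive <- names(calls)[calls == "responsive"]
  st <- classify_sources_targets(annot, responsive, ...)
  if (!is.null(graph)) {
    st$sources <- intersect(st$sources, graph$nodes)
    st$targets <- intersect(st$targets, graph$nodes)
  }
  z <- if (is.null(zmatrix)) stats::setNames(numeric(0), character(0))
       else aggregate_zscore(zmatrix, annot, chemical)
  structure(list(
    chemical = chemical,
    sources = st$sources, targets = st$targets,
    responsive = responsive,
    responsive_intermediates = setdiff(responsive,
                                       c(st$sources, st$targets)),
    nonresponsive = names(calls)[calls == "nonresponsive"],
    zscores = z), class = "toxicant_profile")
}

#' @export
print.toxicant_profile <- function(x, ...) {
  cat("toxicant profile for", x$chemical, "\n",
      " sources (responsive receptors):", length(x$sources), "\n",
      " targets (responsive TFs):      ", length(x$targets), "\n",
      " responsive intermediates:      ", length(x$responsive_intermediates),
      "\n  nonresponsive proteins:        ", length(x$nonresponsive), "\n")
  invisible(x)
}

#' Write / read a per-chemical protein role table
#'
#' TSV with columns `protein`, `role` (`source`, `target`, `intermediate`
#' for responsive intermediates, or `nonresponsive`) and `zscore` (NA when
#' unavailable).
#'
#' @param profile a `toxicant_profile`.
#' @param path file path.
#' @return `write_profile` returns `path` invisibly; `read_profile`
#'   returns a `toxicant_profile` (z-scores only for listed proteins).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "toxicant_profile"))
  prot <- c(profile$sources, profile$targets,
            profile$responsive_intermediates, profile$nonresponsive)
  role <- rep(c("source", "target", "intermediate", "nonresponsive"),
              c(length(profile$sources), length(profile$targets),
                length(profile$responsive_intermediates),
                length(profile$nonresponsive)))
  z <- profile$zscores[prot]
  utils::write.table(
    data.frame(protein = prot, role = role, zscore = as.numeric(z)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param chemical chemical ID to attach when reading.
#' @export
read_profile <- function(path, chemical = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  z <- stats::setNames(df$zscore, df$protein)
  z <- z[!is.na(z)]
  src <- df$protein[df$role == "source"]
  tgt <- df$protein[df$role == "target"]
  mid <- df$protein[df$role == "intermediate"]
  structure(list(chemical = chemical, sources = src, targets = tgt,
                 responsive = c(src, tgt, mid),
                 responsive_intermediates = mid,
                 nonresponsive = df$protein[df$role == "nonresponsive"],
                 zscores = z), class = "toxicant_profile")
}
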