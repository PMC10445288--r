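#' Specification for synthetic test data
#'
#' Describes a small random interactome with planted receptor-to-TF
#' signaling paths, mimicking (at desk scale) the structure of the real
#' background network: a mix of directed (regulatory) and undirected
#' (physical) edges in roughly 1:2 proportion, evidence-style edge weights
#' on (0, 1), and a handful of high-weight planted paths that a correct
#' path-finding run must recover.
#'
#' Planted paths are node- and edge-disjoint, their edges are directed
#' with weights drawn from `planted_weight_range` (>= 0.9), and background
#' weights are Beta-distributed scaled below `max_background_weight`.
#' Background edges never leave a planted source nor enter a planted
#' target; together with the weight separation and planted lengths <= 4
#' this guarantees each planted path is the unique cheapest
#' source-to-target path (see the package vignette for the argument).
#'
#' @param n_nodes number of proteins.
#' @param n_directed,n_undirected background edge counts per pool.
#' @param n_planted number of planted source-to-TF paths.
#' @param planted_length edges per planted path (2-4 for the recovery
#'   guarantee).
#' @param planted_weight_range weight range for planted edges.
#' @param weight_shape1,weight_shape2 Beta parameters for background
#'   weights.
#' @param max_background_weight upper bound for background weights.
#' @param n_chemicals number of synthetic chemicals for hit matrices.
#' @param n_filler_assays unmapped background assays added so chemicals
#'   pass the tested-assay filter.
#' @param seed mandatory integer seed.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 60, n_directed = 80, n_undirected = 40,
                           n_planted = 1, planted_length = 3,
                           planted_weight_range = c(0.9, 0.99),
                           weight_shape1 = 2, weight_shape2 = 2,
                           max_background_weight = 0.8,
                           n_chemicals = 3, n_filler_assays = 600,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  spec <- list(n_nodes = n_nodes, n_directed = n_directed,
               n_undirected = n_undirected, n_planted = n_planted,
               planted_length = planted_length,
               planted_weight_range = planted_weight_range,
               weight_shape1 = weight_shape1, weight_shape2 = weight_shape2,
               max_background_weight = max_background_weight,
               n_chemicals = n_chemicals, n_filler_assays = n_filler_assays,
               seed = as.integer(seed))
  if (planted_length < 2 || planted_length > 4)
    stop("planted_length must be 2-4 (recovery is only guaranteed there)")
  if (n_planted < 0 || n_planted * (planted_length + 1) > n_nodes)
    stop("infeasible spec: planted paths need ",
         n_planted * (planted_length + 1), " distinct nodes, have ", n_nodes)
  if (max_background_weight >= min(planted_weight_range))
    stop("background weights must stay below the planted weight range")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic interactome with planted signaling paths
#'
#' Builds a random mixed directed/undirected weighted graph per the spec
#' and plants `n_planted` disjoint high-weight directed source-to-target
#' paths whose recovery by [edgelinker()] is guaranteed (see
#' [synthetic_spec()]).
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `interactome`, `planted_paths` (list of node
#'   sequences), `sources`, `targets` and the `spec`.
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nodes <- sprintf("P%03d", seq_len(spec$n_nodes))
  L <- spec$planted_length
  planted <- list(); sources <- character(0); targets <- character(0)
  used <- 0L
  ptail <- character(0); phead <- character(0)
  for (i in seq_len(spec$n_planted)) {
    path <- nodes[used + seq_len(L + 1L)]
    used <- used + L + 1L
    planted[[i]] <- path
    sources <- c(sources, path[1L])
    targets <- c(targets, path[L + 1L])
    ptail <- c(ptail, path[-(L + 1L)])
    phead <- c(phead, path[-1L])
  }
  pw <- stats::runif(length(ptail), spec$planted_weight_range[1L],
                     spec$planted_weight_range[2L])

  taken <- new.env(hash = TRUE)
  for (k in paste(ptail, phead, sep = "\r")) assign(k, TRUE, envir = taken)
  draw_pairs <- function(n, ok_tail, ok_head, undirected) {
    t_out <- character(n); h_out <- character(n); got <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 200L * n + 1000L)
        stop("infeasible spec: cannot place ", n, " background edges")
      u <- sample(ok_tail, 1L); v <- sample(ok_head, 1L)
      if (u == v) next
      k1 <- paste(u, v, sep = "\r"); k2 <- paste(v, u, sep = "\r")
      if (exists(k1, envir = taken)) next
      if (undirected && exists(k2, envir = taken)) next
      assign(k1, TRUE, envir = taken)
      if (undirected) assign(k2, TRUE, envir = taken)
      got <- got + 1L
      t_out[got] <- u; h_out[got] <- v
    }
    list(tail = t_out, head = h_out)
  }
  rbw <- function(n) stats::rbeta(n, spec$weight_shape1, spec$weight_shape2) *
    spec$max_background_weight
  # background never leaves a source nor enters a target; undirected
  # background avoids sources and targets entirely (bidirection would
  # otherwise create such edges)
  bd <- draw_pairs(spec$n_directed, setdiff(nodes, sources),
                   setdiff(nodes, targets), undirected = FALSE)
  inner <- setdiff(nodes, c(sources, targets))
  bu <- draw_pairs(spec$n_undirected, inner, inner, undirected = TRUE)
  g <- interactome(
    tail = c(ptail, bd$tail, bu$tail),
    head = c(phead, bd$head, bu$head),
    weight = c(pw, pmax(rbw(spec$n_directed), 1e-6),
               pmax(rbw(spec$n_undirected), 1e-6)),
    directed = c(rep(TRUE, length(ptail) + spec$n_directed),
                 rep(FALSE, spec$n_undirected)),
    evidence = c(rep("planted", length(ptail)),
                 rep("synthetic", spec$n_directed + spec$n_undirected)),
    nodes = nodes)
  list(interactome = g, planted_paths = planted, sources = sources,
       targets = targets, spec = spec)
}

#' Generate a ToxCast-style hit matrix, annotation and z-scores
#'
#' Builds matrices whose parsing by [call_responsive()],
#' [classify_sources_targets()] and [aggregate_zscore()] reproduces the
#' requested per-chemical sources and targets exactly. Receptor proteins
#' get a Novascreen (`NVS`) receptor assay; TFs get an up/down assay pair
#' (only the `_up` member is a hit, exercising the pair-collapse rule);
#' responsive intermediates and nonresponsive proteins get generic enzyme
#' assays; unmapped filler assays (tested, value 0, with a sprinkling of
#' -1/NA) bring every chemical above the tested-assay filter. Optional
#' edge-case assays add a responsive non-NVS receptor, a responsive
#' nuclear-receptor-family protein (both must be excluded from S_x) and
#' an undetermined (-1/NA only) protein.
#'
#' @param profiles list of per-chemical lists/profiles with `chemical`,
#'   `sources`, `targets` and optionally `responsive_intermediates`,
#'   `nonresponsive`.
#' @param n_filler_assays number of unmapped background assays.
#' @param include_edge_cases add the deliberate edge-case assays.
#' @param seed optional seed (for filler -1/NA placement and z-scores).
#' @return A list with `hits` (matrix), `zscores` (matrix), `annotation`
#'   (data.frame).
#' @export
generate_hit_matrix <- function(profiles, n_filler_assays = 600,
                                include_edge_cases = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  get0c <- function(p, f) if (is.null(p[[f]])) character(0) else p[[f]]
  # paste0 turns zero-length args into "", so guard empty protein sets
  pfx <- function(pre, x, suf = "")
    if (length(x)) paste0(pre, x, suf) else character(0)
  all_src <- unique(unlist(lapply(profiles, `[[`, "sources")))
  all_tgt <- unique(unlist(lapply(profiles, `[[`, "targets")))
  all_mid <- unique(unlist(lapply(profiles, get0c, "responsive_intermediates")))
  all_non <- unique(unlist(lapply(profiles, get0c, "nonresponsive")))
  if (length(intersect(all_src, all_tgt)))
    stop("a protein cannot be a source for one chemical and a target for another")
  if (length(intersect(all_mid, c(all_src, all_tgt))))
    stop("responsive intermediates must not be receptor/TF proteins")
  all_non <- setdiff(all_non, c(all_src, all_tgt, all_mid))

  ann <- rbind(
    if (length(all_src)) data.frame(
      assay_id = paste0("NVS_rec_", all_src), protein_id = all_src,
      target_type_sub = "receptor", target_family = "gpcr", vendor = "NVS"),
    if (length(all_tgt)) data.frame(
      assay_id = c(paste0("ATG_", all_tgt, "_up"),
                   paste0("ATG_", all_tgt, "_dn")),
      protein_id = rep(all_tgt, 2L),
      target_type_sub = "transcription factor",
      target_family = "dna binding", vendor = "ATG"),
    if (length(all_mid)) data.frame(
      assay_id = paste0("TOX_enz_", all_mid), protein_id = all_mid,
      target_type_sub = "enzyme", target_family = "kinase", vendor = "TOX21"),
    if (length(all_non)) data.frame(
      assay_id = paste0("ACEA_enz_", all_non), protein_id = all_non,
      target_type_sub = "enzyme", target_family = "kinase", vendor = "ACEA"))
  if (include_edge_cases)
    ann <- rbind(ann, data.frame(
      assay_id = c("ATG_rec_ECNONVS", "NVS_rec_ECNUCREC", "TOX_enz_ECUNDET"),
      protein_id = c("EC_NONVS", "EC_NUCREC", "EC_UNDET"),
      target_type_sub = c("receptor", "receptor", "enzyme"),
      target_family = c("gpcr", "nuclear receptor", "kinase"),
      vendor = c("ATG", "NVS", "TOX21")))
  if (n_filler_assays > 0L)
    ann <- rbind(ann, data.frame(
      assay_id = sprintf("BSK_bg_%04d", seq_len(n_filler_assays)),
      protein_id = "", target_type_sub = "cell-based",
      target_family = "background measurement", vendor = "BSK"))
  ann <- annotate_assay_directions(ann)

  chems <- vapply(profiles, `[[`, "", "chemical")
  hits <- matrix(NA_real_, nrow = length(chems), ncol = nrow(ann),
                 dimnames = list(chems, ann$assay_id))
  zs <- hits
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    src <- p$sources; tgt <- p$targets
    mid <- get0c(p, "responsive_intermediates")
    non <- setdiff(get0c(p, "nonresponsive"), c(src, tgt, mid))
    hit1 <- c(pfx("NVS_rec_", src), pfx("ATG_", tgt, "_up"),
              pfx("TOX_enz_", mid))
    hits[i, hit1] <- 1
    hits[i, pfx("ATG_", tgt, "_dn")] <- 0
    hits[i, pfx("ACEA_enz_", non)] <- 0
    zs[i, hit1] <- abs(stats::rnorm(length(hit1), mean = 3, sd = 1))
    if (include_edge_cases && i == 1L) {
      hits[i, c("ATG_rec_ECNONVS", "NVS_rec_ECNUCREC")] <- 1
      hits[i, "TOX_enz_ECUNDET"] <- -1
      zs[i, c("ATG_rec_ECNONVS", "NVS_rec_ECNUCREC")] <-
        abs(stats::rnorm(2, 3, 1))
    }
    if (n_filler_assays > 0L) {
      fill <- sprintf("BSK_bg_%04d", seq_len(n_filler_assays))
      v <- sample(c(0, -1, NA_real_), n_filler_assays, replace = TRUE,
                  prob = c(0.9, 0.05, 0.05))
      hits[i, fill] <- v
    }
  }
  list(hits = hits, zscores = zs, annotation = ann)
}

#' Generate a CTD-style chemical-gene interaction table
#'
#' Builds a toy table in the CTD layout (`ChemicalName`, `GeneSymbol`,
#' `Organism`, `Interaction`, `InteractionActions`) whose
#' (de)phosphorylation rows reproduce the requested per-chemical gene
#' sets, plus decoy rows (expression interactions and a non-human
#' organism) that a correct parser must drop.
#'
#' @param gene_sets named list: chemical -> character vector of genes with
#'   phospho evidence.
#' @param n_decoys decoy rows per chemical (default 2).
#' @param seed optional seed.
#' @return A data.frame in CTD layout.
#' @export
generate_ctd <- function(gene_sets, n_decoys = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(gene_sets), function(chem) {
    genes <- gene_sets[[chem]]
    verbs <- sample(c("increased phosphorylation of",
                      "decreased phosphorylation of",
                      "increased dephosphorylation of"),
                    length(genes), replace = TRUE)
    keep <- data.frame(
      ChemicalName = chem, GeneSymbol = genes, Organism = "Homo sapiens",
      Interaction = paste(verbs, genes, "protein"),
      InteractionActions = sub(" of.*", "", verbs))
    if (n_decoys == 0L) return(keep)
    dg <- paste0("DECOY", seq_len(n_decoys))
    decoy <- data.frame(
      ChemicalName = chem, GeneSymbol = dg,
      Organism = c("Homo sapiens",
                   rep("Mus musculus", n_decoys - 1L))[seq_len(n_decoys)],
      Interaction = c(paste("increased expression of", dg[1L], "mRNA"),
                      paste("increased phosphorylation of",
                            dg[-1L], "protein"))[seq_len(n_decoys)],
      InteractionActions = "decoy")
    rbind(keep, decoy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write synthetic fixtures in the formats the parsers read
#'
#' Writes the raw interactome edge table, hit/z-score CSV matrices and the
#' assay annotation TSV into a directory.
#'
#' @param gen result of [generate_interactome()].
#' @param tox result of [generate_hit_matrix()] (optional).
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic <- function(gen, tox = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(interactome = file.path(dir, "interactome.tsv"))
  write_interactome(gen$interactome, files[["interactome"]])
  writeLines(gen$sources, file.path(dir, "sources.txt"))
  writeLines(gen$targets, file.path(dir, "targets.txt"))
  files <- c(files, sources = file.path(dir, "sources.txt"),
             targets = file.path(dir, "targets.txt"))
  if (!is.null(tox)) {
    utils::write.csv(tox$hits, file.path(dir, "hit_matrix.csv"))
    utils::write.csv(tox$zscores, file.path(dir, "zscore_matrix.csv"))
    utils::write.table(
      tox$annotation[, c("assay_id", "protein_id", "target_type_sub",
                         "target_family", "vendor")],
      file.path(dir, "assay_annotation.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    files <- c(files, hits = file.path(dir, "hit_matrix.csv"),
               zscores = file.path(dir, "zscore_matrix.csv"),
               annotation = file.path(dir, "assay_annotation.tsv"))
  }
  invisible(files)
}
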