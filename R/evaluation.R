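#' Parse CTD-style chemical-gene interactions into phospho gene sets
#'
#' Keeps rows whose organism is human and whose interaction text contains
#' "phosphorylation" or "dephosphorylation" (case-insensitive substring;
#' "dephosphorylation" contains "phosphorylation", so one pattern covers
#' both), then groups the gene symbols by chemical. These
#' (de)phosphorylation records serve as a proxy gold standard for
#' signaling effects of chemical exposure.
#'
#' @param x a file path to a TSV or a data.frame with columns
#'   `ChemicalName`, `GeneSymbol`, `Organism` and `Interaction`
#'   (case-insensitive names).
#' @return A named list mapping each chemical to its sorted, deduplicated
#'   character vector of gene symbols.
#' @export
parse_ctd <- function(x) {
  df <- if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE)
        else as.data.frame(x)
  need <- c("ChemicalName", "GeneSymbol", "Organism", "Interaction")
  idx <- match(tolower(need), tolower(names(df)))
  if (anyNA(idx))
    stop("CTD table is missing column(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  names(df)[idx] <- need
  human <- tolower(df$Organism) %in% c("homo sapiens", "human")
  phos <- grepl("phosphorylation", tolower(df$Interaction), fixed = TRUE)
  df <- df[human & phos & nzchar(df$GeneSymbol), , drop = FALSE]
  lapply(split(df$GeneSymbol, df$ChemicalName), function(g) sort(unique(g)))
}

#' Hypergeometric overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a network's gene set and a CTD phospho gene set when
#' drawing `|network|` genes from a universe containing `|ctd|` successes.
#'
#' @param network_genes character vector of genes in the signaling
#'   network (after protein-to-gene mapping).
#' @param ctd_genes character vector of CTD phospho genes for the
#'   chemical.
#' @param universe_size size of the background universe (defaults in the
#'   pipeline to the interactome node count); must be at least the size of
#'   the union of the two sets.
#' @return A list with `overlap` (count) and `p` (hypergeometric p-value).
#' @export
overlap_test <- function(network_genes, ctd_genes, universe_size) {
  network_genes <- unique(network_genes)
  ctd_genes <- unique(ctd_genes)
  if (universe_size < length(union(network_genes, ctd_genes)))
    stop("universe_size is smaller than the union of the two gene sets")
  ov <- length(intersect(network_genes, ctd_genes))
  p <- stats::phyper(ov - 1, m = length(ctd_genes),
                     n = universe_size - length(ctd_genes),
                     k = length(network_genes), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Summary statistics of a signaling network
#'
#' Reports the node count, edge count, fraction of directed (regulatory)
#' edges, average path length (mean number of edges across the retained
#' paths) and, when a profile is supplied, the recall fractions of the
#' chemical's responsive and nonresponsive intermediate proteins: the
#' fraction of ToxCast-responsive (resp. nonresponsive) proteins, other
#' than the input receptors and TFs, that appear in the network. Recall is
#' `NA` when the corresponding denominator is empty.
#'
#' @param net a `signaling_network` from [edgelinker()].
#' @param profile optional [toxicant_profile()].
#' @return A one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `frac_directed`, `avg_path_len`, `recall_responsive`,
#'   `recall_nonresponsive`.
#' @export
network_summary <- function(net, profile = NULL) {
  stopifnot(inherits(net, "signaling_network"))
  lens <- if (nrow(net$paths))
    vapply(strsplit(net$paths$path, "|", fixed = TRUE), length, 1L) - 1L
  else integer(0)
  frac_dir <- if (!is.null(net$edges$orientation) && nrow(net$edges))
    mean(net$edges$orientation == "directed") else NA_real_
  rec <- function(set) {
    pool <- setdiff(set, c(profile$sources, profile$targets))
    if (length(pool) == 0L) return(NA_real_)
    length(intersect(pool, net$nodes)) / length(pool)
  }
  data.frame(
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    frac_directed = frac_dir,
    avg_path_len = if (length(lens)) mean(lens) else NA_real_,
    recall_responsive =
      if (is.null(profile)) NA_real_ else rec(profile$responsive_intermediates),
    recall_nonresponsive =
      if (is.null(profile)) NA_real_ else rec(profile$nonresponsive))
}

#' Evaluate signaling networks against CTD phospho evidence
#'
#' For each network, maps its proteins to gene symbols, intersects them
#' with the chemical's CTD (de)phosphorylation gene set and computes the
#' hypergeometric overlap p-value; BH q-values are computed across all
#' chemicals that have CTD evidence. Unmapped proteins are dropped with a
#' message.
#'
#' @param nets a list of `signaling_network` objects (with `chemical`
#'   set).
#' @param ctd a CTD phospho set from [parse_ctd()].
#' @param universe_size hypergeometric background size (e.g. the
#'   interactome node count).
#' @param mapping optional two-column data.frame (protein, gene); `NULL`
#'   uses protein IDs as gene symbols.
#' @param profiles optional named list of profiles (by chemical) for
#'   recall columns.
#' @return A data.frame with one row per network: `chemical`, `n_nodes`,
#'   `n_edges`, `avg_path_len`, `ctd_overlap`, `ctd_p`, `ctd_q` (`NA`
#'   where the chemical has no CTD evidence).
#' @export
evaluate_networks <- function(nets, ctd, universe_size, mapping = NULL,
                              profiles = NULL) {
  map_genes <- function(prot) {
    if (is.null(mapping)) return(prot)
    g <- mapping[[2L]][match(prot, mapping[[1L]])]
    n_drop <- sum(is.na(g))
    if (n_drop) message(n_drop, " unmapped protein(s) dropped")
    unique(g[!is.na(g)])
  }
  rows <- lapply(nets, function(net) {
    chem <- net$chemical
    prof <- if (!is.null(profiles)) profiles[[chem]] else NULL
    s <- network_summary(net, prof)
    genes <- map_genes(net$nodes)
    if (!is.null(chem) && chem %in% names(ctd)) {
      ot <- overlap_test(genes, ctd[[chem]], universe_size)
      ov <- ot$overlap; p <- ot$p
    } else {
      ov <- NA_integer_; p <- NA_real_
    }
    data.frame(chemical = if (is.null(chem)) NA_character_ else chem,
               n_nodes = s$n_nodes, n_edges = s$n_edges,
               avg_path_len = s$avg_path_len,
               ctd_overlap = ov, ctd_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ctd_q <- NA_real_
  tested <- !is.na(out$ctd_p)
  if (any(tested)) out$ctd_q[tested] <- bh_qvalues(out$ctd_p[tested])
  rownames(out) <- NULL
  out
}
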