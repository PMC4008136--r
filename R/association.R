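#' Build basal + extension regulatory domains
#'
#' Each gene gets a basal domain around its TSS (`basal_up` bp upstream
#' to `basal_down` bp downstream, strand-aware) and an extended domain:
#' the basal domain grown by up to `max_ext` bp on each side, truncated
#' at the neighbouring genes' basal domains and at coordinate 0. The
#' basal domain is always contained in the extended domain; extended
#' domains never cross a neighbour's basal boundary (except where two
#' basal domains themselves overlap, in which case containment of the
#' own basal domain takes priority).
#'
#' @param genes gene-model data.frame (see [generate_gene_models()]).
#' @param basal_up,basal_down basal extent upstream/downstream of the
#'   TSS in bp (defaults 5000 / 1000).
#' @param max_ext maximum extension beyond the basal domain per side in
#'   bp (default 1e6).
#' @return data.frame `gene_id, chrom, strand, basal_start, basal_end,
#'   ext_start, ext_end` (0-based half-open).
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000,
                                     basal_down = 1000, max_ext = 1e6) {
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), basal_start = integer(0),
                      basal_end = integer(0), ext_start = integer(0),
                      ext_end = integer(0), stringsAsFactors = FALSE))
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  b_start <- pmax(0, ifelse(genes$strand == "+", tss - basal_up,
                            tss - basal_down))
  b_end <- ifelse(genes$strand == "+", tss + basal_down, tss + basal_up)
  dom <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, basal_start = b_start,
                    basal_end = b_end, stringsAsFactors = FALSE)
  dom <- dom[order(dom$chrom, dom$basal_start), , drop = FALSE]
  out <- lapply(split(dom, dom$chrom), function(d) {
    n <- nrow(d)
    prev_end <- c(0, cummax(d$basal_end))[seq_len(n)]
    nxt_start <- c(d$basal_start[-1], Inf)
    d$ext_start <- pmin(d$basal_start,
                        pmax(d$basal_start - max_ext, prev_end, 0))
    d$ext_end <- pmax(d$basal_end,
                      pmin(d$basal_end + max_ext, nxt_start))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

domains_granges <- function(domains, which = c("ext", "basal")) {
  which <- match.arg(which)
  s <- domains[[paste0(which, "_start")]]
  e <- domains[[paste0(which, "_end")]]
  GenomicRanges::GRanges(domains$chrom, IRanges::IRanges(s + 1L, e))
}

#' Associate genomic regions with genes through regulatory domains
#'
#' A region is associated with every gene whose extended regulatory
#' domain it intersects.
#'
#' @param regions data.frame with `chrom, start, end, island_id`
#'   (0-based half-open).
#' @param domains output of [build_regulatory_domains()].
#' @return list with `region_genes`: named list mapping each region id
#'   to its associated gene ids (empty vector when none).
#' @export
associate_regions <- function(regions, domains) {
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  hits <- GenomicRanges::findOverlaps(gr_r, domains_granges(domains, "ext"))
  qh <- S4Vectors::queryHits(hits)
  genes <- domains$gene_id[S4Vectors::subjectHits(hits)]
  rg <- split(genes, factor(regions$island_id[qh],
                            levels = regions$island_id))
  list(region_genes = lapply(rg, unique))
}

#' Split associated genes into IRDM-linked and other
#'
#' Genes associated with at least one called (IRDM) region form the
#' IRDM-G set; genes associated only with uncalled regions form
#' N-IRDM-G. A gene associated with both kinds of region is assigned to
#' IRDM-G, keeping the two groups disjoint.
#'
#' @param regions region data.frame covering the analysis universe.
#' @param irdm_ids ids of the called regions.
#' @param domains regulatory domains.
#' @return list with character vectors `irdm_g` and `n_irdm_g`.
#' @export
associate_gene_sets <- function(regions, irdm_ids, domains) {
  assoc <- associate_regions(regions, domains)$region_genes
  is_irdm <- names(assoc) %in% irdm_ids
  irdm_g <- sort(unique(unlist(assoc[is_irdm], use.names = FALSE)))
  other <- sort(unique(unlist(assoc[!is_irdm], use.names = FALSE)))
  list(irdm_g = irdm_g, n_irdm_g = setdiff(other, irdm_g))
}

coverage_fraction <- function(gr, genome_bp) {
  sum(IRanges::width(GenomicRanges::reduce(gr))) / genome_bp
}

#' Term enrichment over regions (binomial) and genes (hypergeometric)
#'
#' For every annotation term, two one-sided enrichment tests in the
#' style of region-based annotation tools: a binomial test over
#' regions, where a region "hits" the term when it intersects the
#' union of the term genes' extended domains and the null hit
#' probability is the fraction of the analysable genome covered by
#' that union; and a hypergeometric test over genes, drawing the
#' region-associated genes from the gene universe and counting those
#' annotated with the term. Both p-value families are BH-corrected and
#' a term is reported enriched only when both q-values are at most
#' `alpha`.
#'
#' @param regions data.frame of query regions (`chrom, start, end,
#'   island_id`).
#' @param domains regulatory domains of all genes.
#' @param term_map data.frame `gene_id, term_id`.
#' @param universe character vector of all gene ids (non-empty).
#' @param genome_bp analysable genome size in bp; default is the total
#'   span covered per chromosome by the domains (a dataset-dependent
#'   stand-in for an annotated-genome size).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame per term: `term_id, n_term_genes, region_hits,
#'   n_regions, p_binom, assoc_in_term, n_assoc, p_hyper, q_binom,
#'   q_hyper, enriched`.
#' @export
term_enrichment <- function(regions, domains, term_map, universe,
                            genome_bp = NULL, alpha = 0.05) {
  if (length(universe) == 0) stop("empty gene universe")
  if (nrow(term_map) == 0) stop("empty term map")
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  if (is.null(genome_bp)) {
    spans <- tapply(domains$ext_end, domains$chrom, max)
    genome_bp <- sum(as.numeric(spans))
  }
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  assoc <- associate_regions(regions, domains)$region_genes
  assoc_genes <- unique(unlist(assoc, use.names = FALSE))
  n_regions <- nrow(regions)
  n_assoc <- length(assoc_genes)

  rows <- lapply(split(term_map$gene_id, term_map$term_id), function(g) {
    g <- unique(g)
    d <- domains[domains$gene_id %in% g, , drop = FALSE]
    gr_t <- GenomicRanges::reduce(domains_granges(d, "ext"))
    p_hit <- min(1, coverage_fraction(gr_t, genome_bp))
    k <- sum(IRanges::overlapsAny(gr_r, gr_t))
    p_binom <- if (p_hit >= 1) 1 else
      stats::pbinom(k - 1, n_regions, p_hit, lower.tail = FALSE)
    k_g <- length(intersect(assoc_genes, g))
    p_hyper <- stats::phyper(k_g - 1, length(g),
                             length(universe) - length(g), n_assoc,
                             lower.tail = FALSE)
    data.frame(n_term_genes = length(g), region_hits = k,
               n_regions = n_regions, p_binom = p_binom,
               assoc_in_term = k_g, n_assoc = n_assoc,
               p_hyper = p_hyper, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(term_id = rownames(res), stringsAsFactors = FALSE),
               res)
  rownames(res) <- NULL
  res$q_binom <- stats::p.adjust(res$p_binom, "BH")
  res$q_hyper <- stats::p.adjust(res$p_hyper, "BH")
  res$enriched <- res$q_binom <= alpha & res$q_hyper <= alpha
  res
}

#' Replica expression divergence (DR) per gene
#'
#' `DR = |expr1 - expr2| / (expr1 + expr2)`, in `[0,1]`; 0 iff the
#' replicas agree, 1 iff exactly one replica is zero. Genes with
#' `expr1 + expr2 = 0` are excluded (their count is reported in the
#' `n_excluded` attribute).
#'
#' @param expr data.frame `gene_id, expr1, expr2`.
#' @return data.frame `gene_id, expr1, expr2, DR`.
#' @export
compute_dr <- function(expr) {
  tot <- expr$expr1 + expr$expr2
  keep <- tot > 0
  out <- expr[keep, , drop = FALSE]
  out$DR <- abs(out$expr1 - out$expr2) / (out$expr1 + out$expr2)
  attr(out, "n_excluded") <- sum(!keep)
  rownames(out) <- NULL
  out
}

#' Median-split Fisher test of replica expression divergence
#'
#' Computes DR for every gene, splits all values at the merged-group
#' median (values strictly above vs at-or-below), and tests the
#' resulting 2x2 table (group x median side) with a two-sided Fisher
#' exact test. A significant p indicates that genes near called
#' regions diverge between replicas differently from the rest.
#'
#' @param expr data.frame `gene_id, expr1, expr2`.
#' @param irdm_genes gene ids of the called-region group (IRDM-G);
#'   remaining genes in `expr` form the comparison group.
#' @return list with `table` (2x2 counts), `p_value`, `median`,
#'   `n_excluded`.
#' @export
dr_fisher_test <- function(expr, irdm_genes) {
  dr <- compute_dr(expr)
  grp <- factor(ifelse(dr$gene_id %in% irdm_genes, "IRDM-G", "N-IRDM-G"),
                levels = c("IRDM-G", "N-IRDM-G"))
  if (any(table(grp) == 0)) stop("both gene groups must be non-empty")
  med <- stats::median(dr$DR)
  side <- factor(ifelse(dr$DR > med, "above", "at_or_below"),
                 levels = c("above", "at_or_below"))
  tab <- table(grp, side)
  list(table = tab, p_value = stats::fisher.test(tab)$p.value,
       median = med, n_excluded = attr(dr, "n_excluded"))
}
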