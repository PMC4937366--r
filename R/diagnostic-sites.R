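#' Call branch-diagnostic mtDNA sites from an aligned genome panel
#'
#' In `branch_specific` mode an alignment column is diagnostic for a hominin
#' branch (modern_human, neanderthal, denisova_sh) when every genome of that
#' branch carries one allele and every other hominin genome *and* the
#' outgroup share a single different allele; the branch allele is derived,
#' the shared allele ancestral. In `pairwise` mode a column is reported when
#' all Neanderthal genomes share one allele and all modern-human genomes
#' share a different one, the other groups being ignored — the expanded site
#' set used when a specimen is assumed to belong to one of those two
#' lineages. Columns containing gaps or ambiguity codes in the genomes the
#' mode consults are excluded.
#'
#' For pairwise sites the outgroup assigns polarity when it matches one of
#' the two alleles; otherwise the site is returned unpolarized
#' (`polarized = FALSE`) with the modern-human allele in the `derived`
#' column by convention.
#'
#' @param panel A [lineage_panel][generate_panel] (or any object with the
#'   same `genomes` tibble).
#' @param mode `"branch_specific"`, `"pairwise"`, or `"both"`.
#' @return Tibble of diagnostic sites: `pos` (1-based alignment/reference
#'   position), `branch`, `derived`, `ancestral`, `transition` (`TRUE` when
#'   the two alleles differ by C<->T or G<->A, i.e. the site is
#'   deamination-prone), `polarized`.
#' @examples
#' panel <- generate_panel(seed = 7, genome_length = 400, n_sites_per_branch = 2)
#' find_diagnostic_sites(panel)
#' @export
find_diagnostic_sites <- function(panel, mode = c("branch_specific", "pairwise", "both")) {
  mode <- match.arg(mode)
  genomes <- panel$genomes
  lens <- nchar(genomes$seq)
  if (length(unique(lens)) != 1L) abort("panel genomes are not aligned")
  L <- lens[[1L]]

  lineage_of <- split(seq_len(nrow(genomes)), genomes$lineage)
  chars <- stringr::str_split(toupper(genomes$seq), "", simplify = TRUE)  # genomes x L

  # per-lineage column allele: the shared base when the lineage is uniform
  # and unambiguous at that column, NA otherwise
  lineage_allele <- function(lin) {
    m <- chars[lineage_of[[lin]], , drop = FALSE]
    allele <- m[1L, ]
    uniform <- colSums(m != matrix(allele, nrow(m), L, byrow = TRUE)) == 0L
    ok <- uniform & allele %in% c("A", "C", "G", "T")
    ifelse(ok, allele, NA_character_)
  }

  present <- names(lineage_of)
  hominins <- c("modern_human", "neanderthal", "denisova_sh")

  out <- list()
  if (mode %in% c("branch_specific", "both")) {
    if (!"outgroup" %in% present) {
      abort("branch_specific mode requires an outgroup in the panel")
    }
    al <- lapply(setNames(nm = present), lineage_allele)
    for (br in intersect(hominins, present)) {
      others <- setdiff(present, br)
      other_mat <- do.call(rbind, al[others])
      other_shared <- apply(other_mat, 2L, function(v) {
        if (anyNA(v)) NA_character_ else if (length(unique(v)) == 1L) v[[1L]] else NA_character_
      })
      hit <- !is.na(al[[br]]) & !is.na(other_shared) & al[[br]] != other_shared
      if (any(hit)) {
        out[[br]] <- tibble(pos = which(hit), branch = br,
                            derived = al[[br]][hit], ancestral = other_shared[hit],
                            polarized = TRUE)
      }
    }
  }
  if (mode %in% c("pairwise", "both")) {
    if (!all(c("modern_human", "neanderthal") %in% present)) {
      abort("pairwise mode requires modern_human and neanderthal genomes")
    }
    a_mh <- lineage_allele("modern_human")
    a_ne <- lineage_allele("neanderthal")
    a_out <- if ("outgroup" %in% present) lineage_allele("outgroup") else rep(NA_character_, L)
    hit <- !is.na(a_mh) & !is.na(a_ne) & a_mh != a_ne
    if (any(hit)) {
      og <- a_out[hit]
      mh <- a_mh[hit]
      ne <- a_ne[hit]
      pol <- !is.na(og) & (og == mh | og == ne)
      der <- ifelse(pol & og == mh, ne, mh)  # non-outgroup allele is derived
      anc <- ifelse(pol & og == mh, mh, ne)
      out[["pairwise"]] <- tibble(pos = which(hit), branch = "pairwise_nea_vs_mh",
                                  derived = der, ancestral = anc, polarized = pol)
    }
  }

  if (length(out) == 0L) return(empty_sites())
  bind_rows(out) %>%
    mutate(transition = is_ct_or_ga(.data$derived, .data$ancestral)) %>%
    select("pos", "branch", "derived", "ancestral", "transition", "polarized") %>%
    arrange(.data$pos, .data$branch)
}

#' Write diagnostic sites as a BED-like TSV
#'
#' Columns: 1-based position, branch, derived allele, ancestral allele.
#'
#' @param sites Tibble from [find_diagnostic_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}
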