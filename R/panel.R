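#' Generate a synthetic hominin mtDNA genome panel with planted diagnostic sites
#'
#' Builds an aligned panel of synthetic mitochondrial genomes for four
#' lineages — `modern_human`, `neanderthal`, `denisova_sh` (the Denisovan /
#' Sima de los Huesos clade) and an `outgroup` (chimpanzee analogue) — in
#' which a known number of alignment columns are branch-diagnostic: one
#' lineage carries a derived allele while every other lineage and the
#' outgroup share a single ancestral allele. Optionally, additional columns
#' are planted that differ between Neanderthal and modern human regardless
#' of the other groups (the "pairwise" expanded site set). All remaining
#' columns are identical across every genome, so the planted sites are the
#' complete ground truth for [find_diagnostic_sites()].
#'
#' Pairwise columns give the Denisova/SH clade and the outgroup a third
#' allele, so that a pairwise column is never simultaneously
#' branch-diagnostic and so that its derived/ancestral polarity cannot be
#' resolved by the outgroup (such sites are returned with
#' `polarized = FALSE`, the modern-human allele occupying the `derived`
#' slot by convention).
#'
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param genome_length Alignment length in bp (>= 200).
#' @param n_sites_per_branch Number of diagnostic columns planted per
#'   hominin branch (modern_human, neanderthal, denisova_sh).
#' @param n_pairwise_sites Number of additional Neanderthal-vs-modern-human
#'   columns planted.
#' @param n_genomes Named integer vector giving the number of genomes per
#'   lineage; the outgroup must be non-empty.
#' @return A `lineage_panel`: a list with `genomes` (tibble of `lineage`,
#'   `genome_id`, `seq`), `truth_sites` (tibble of planted
#'   [DiagnosticSite][find_diagnostic_sites] rows), `length`, and `seed`.
#' @examples
#' panel <- generate_panel(seed = 1, genome_length = 500, n_sites_per_branch = 3)
#' panel$truth_sites
#' @export
generate_panel <- function(seed,
                           genome_length = 1000L,
                           n_sites_per_branch = 5L,
                           n_pairwise_sites = 0L,
                           n_genomes = c(modern_human = 3L, neanderthal = 2L,
                                         denisova_sh = 1L, outgroup = 1L)) {
  if (genome_length < 200L) {
    abort("genome_length must be at least 200")
  }
  if (n_sites_per_branch < 0L || n_pairwise_sites < 0L) {
    abort("site counts must be non-negative")
  }
  lineages <- c("modern_human", "neanderthal", "denisova_sh", "outgroup")
  if (!all(lineages %in% names(n_genomes)) || n_genomes[["outgroup"]] < 1L) {
    abort("n_genomes must name all four lineages and include a non-empty outgroup")
  }
  hominin_branches <- c("modern_human", "neanderthal", "denisova_sh")
  n_total_sites <- 3L * n_sites_per_branch + n_pairwise_sites
  if (n_total_sites > genome_length) {
    abort(paste0("genome_length ", genome_length, " is too small to place ",
                 n_total_sites, " diagnostic sites"))
  }

  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, genome_length, replace = TRUE)
  cols <- setNames(replicate(4, root, simplify = FALSE), lineages)

  site_pos <- if (n_total_sites > 0L) sort(sample.int(genome_length, n_total_sites)) else integer(0)
  site_branch <- rep(c(hominin_branches, "pairwise_nea_vs_mh"),
                     times = c(rep(n_sites_per_branch, 3L), n_pairwise_sites))
  site_branch <- sample(site_branch)  # interleave branches along the genome

  truth <- vector("list", n_total_sites)
  for (k in seq_len(n_total_sites)) {
    pos <- site_pos[k]
    br <- site_branch[k]
    anc <- root[pos]
    if (br %in% hominin_branches) {
      der <- sample(setdiff(bases, anc), 1L)
      cols[[br]][pos] <- der
      truth[[k]] <- tibble(pos = pos, branch = br, derived = der,
                           ancestral = anc, polarized = TRUE)
    } else {
      # three distinct alleles: MH, NEA, and everyone else (incl. outgroup)
      pick <- sample(setdiff(bases, anc), 2L)
      cols[["modern_human"]][pos] <- pick[1L]
      cols[["neanderthal"]][pos] <- pick[2L]
      truth[[k]] <- tibble(pos = pos, branch = br, derived = pick[1L],
                           ancestral = pick[2L], polarized = FALSE)
    }
  }
  truth_sites <- if (n_total_sites > 0L) {
    bind_rows(truth) %>%
      mutate(transition = is_ct_or_ga(.data$derived, .data$ancestral)) %>%
      select("pos", "branch", "derived", "ancestral", "transition", "polarized") %>%
      arrange(.data$pos)
  } else {
    empty_sites()
  }

  genomes <- purrr::map(lineages, function(lin) {
    tibble(lineage = lin,
           genome_id = paste0(lin, "_", seq_len(n_genomes[[lin]])),
           seq = paste(cols[[lin]], collapse = ""))
  }) %>% bind_rows()

  structure(list(genomes = genomes, truth_sites = truth_sites,
                 length = genome_length, seed = seed),
            class = "lineage_panel")
}

is_ct_or_ga <- function(a, b) {
  (a == "C" & b == "T") | (a == "T" & b == "C") |
    (a == "G" & b == "A") | (a == "A" & b == "G")
}

empty_sites <- function() {
  tibble(pos = integer(0), branch = character(0), derived = character(0),
         ancestral = character(0), transition = logical(0), polarized = logical(0))
}

#' @export
print.lineage_panel <- function(x, ...) {
  n_by_lineage <- dplyr::count(x$genomes, .data$lineage)
  cat("<lineage_panel> alignment length", x$length, "bp\n")
  for (i in seq_len(nrow(n_by_lineage))) {
    cat("  ", n_by_lineage$lineage[i], ": ", n_by_lineage$n[i], " genome(s)\n", sep = "")
  }
  cat("  planted diagnostic sites:", nrow(x$truth_sites), "\n")
  invisible(x)
}

#' Analysis reference sequence of a panel
#'
#' The first modern-human genome, playing the role the rCRS plays for real
#' data: simulated fragments are placed in, and diagnostic sites expressed
#' in, this sequence's coordinates. All panel genomes are aligned and
#' gap-free, so alignment columns and reference positions coincide.
#'
#' @param panel A [lineage_panel][generate_panel].
#' @return Character scalar.
#' @export
panel_reference <- function(panel) {
  stopifnot(inherits(panel, "lineage_panel"))
  panel$genomes %>%
    filter(.data$lineage == "modern_human") %>%
    slice(1L) %>%
    pull("seq")
}

lineage_genome <- function(panel, lineage, which = 1L) {
  seqs <- panel$genomes$seq[panel$genomes$lineage == lineage]
  if (length(seqs) < which) {
    abort(paste0("unknown or empty lineage: ", lineage))
  }
  seqs[[which]]
}

#' Write / read an aligned genome panel as FASTA
#'
#' Sequence names are `lineage|genome_id`; the gap character `-` is allowed.
#' Reading back recovers the genomes but not the planted truth sites (which
#' only the generator knows).
#'
#' @param panel A [lineage_panel][generate_panel].
#' @param path File path.
#' @return `write_panel_fasta()` returns `path` invisibly;
#'   `read_panel_fasta()` returns a `lineage_panel` with empty `truth_sites`.
#' @export
write_panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "lineage_panel"))
  seqs <- Biostrings::DNAStringSet(panel$genomes$seq)
  names(seqs) <- paste(panel$genomes$lineage, panel$genomes$genome_id, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lens <- Biostrings::width(seqs)
  if (length(seqs) == 0L) abort("empty panel FASTA")
  if (length(unique(lens)) != 1L) abort("panel sequences are not aligned (unequal lengths)")
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 2L)
  genomes <- tibble(lineage = parts[, 1L],
                    genome_id = ifelse(parts[, 2L] == "", parts[, 1L], parts[, 2L]),
                    seq = unname(toupper(as.character(seqs))))
  structure(list(genomes = genomes, truth_sites = empty_sites(),
                 length = lens[[1L]], seed = NA_integer_),
            class = "lineage_panel")
}
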