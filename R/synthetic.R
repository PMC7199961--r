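# Seeded synthetic-data generator. The planted signal follows canonical
# miRNA targeting: a positive target site contains the reverse complement
# of the miRNA seed (nucleotides 2-8), optionally plus a 3'-supplementary
# block, embedded in random sequence context; negatives are pseudo sites
# drawn from transcript regions exactly as the real negative-set
# construction does (7:2:1 over 3'UTR/5'UTR/ORF), so the fixture exercises
# the same chimera-building code path as real data.

#' Configuration for the synthetic dataset generator
#'
#' Defaults define a planted-motif benchmark in the regime this
#' architecture can learn at fixture scale (a few thousand chimeras): a
#' single miRNA whose positives carry both a seed complement and a 6-nt
#' 3'-supplementary complement, degraded by 5% per-base mutation. See the
#' methods vignette for the design study behind these values and what the
#' fixture does and does not emulate about CLASH-derived data.
#'
#' @param n_mirnas number of distinct miRNAs (default 1).
#' @param mirna_length miRNA length in nt (default 21).
#' @param n_transcripts number of synthetic transcripts (default 60).
#' @param region_lengths named lengths of the `UTR5`, `ORF`, `UTR3`
#'   segments of every transcript (defaults 200, 900, 400 nt).
#' @param n_pos,n_neg number of positive / negative chimeras (defaults
#'   2500 each).
#' @param n_heldout rows reserved as a held-out table (default 500).
#' @param seed_match_mode `"seed_plus_3prime"` (default: plant the 7-nt
#'   seed complement plus a 6-nt complement to miRNA nt 13-18, emulating
#'   canonical seed pairing with 3'-supplementary pairing) or `"seed_2_8"`
#'   (seed complement only, a strictly weaker signal).
#' @param mutation_rate per-base probability of mutating the target site
#'   after planting (in [0, 0.3]; default 0.05).
#' @param seed master integer seed (default 1).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_mirnas = 1L, mirna_length = 21L,
                         n_transcripts = 60L,
                         region_lengths = c(UTR5 = 200L, ORF = 900L,
                                            UTR3 = 400L),
                         n_pos = 2500L, n_neg = 2500L, n_heldout = 500L,
                         seed_match_mode = c("seed_plus_3prime",
                                             "seed_2_8"),
                         mutation_rate = 0.05, seed = 1L) {
  seed_match_mode <- match.arg(seed_match_mode)
  stopifnot(n_mirnas >= 1L, mirna_length >= 10L, n_transcripts >= 1L,
            n_pos >= 0L, n_neg >= 0L, n_heldout >= 0L,
            n_heldout < n_pos + n_neg,
            mutation_rate >= 0, mutation_rate <= 0.3,
            all(c("UTR5", "ORF", "UTR3") %in% names(region_lengths)))
  structure(list(n_mirnas = as.integer(n_mirnas),
                 mirna_length = as.integer(mirna_length),
                 n_transcripts = as.integer(n_transcripts),
                 region_lengths = region_lengths, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg),
                 n_heldout = as.integer(n_heldout),
                 seed_match_mode = seed_match_mode,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "synth_config")
}

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate random miRNA records
#'
#' @param config a [synth_config()].
#' @param seed optional seed override.
#' @return `data.frame` with unique `id` and uniform-base `seq`.
#' @export
gen_mirnas <- function(config = synth_config(), seed = config$seed) {
  with_seed_(derive_seed(seed, 11L), {
    data.frame(
      id = sprintf("mir-%03d", seq_len(config$n_mirnas)),
      seq = vapply(seq_len(config$n_mirnas),
                   function(i) random_rna(config$mirna_length),
                   character(1)),
      stringsAsFactors = FALSE)
  })
}

#' Generate annotated synthetic transcripts
#'
#' Each transcript is the concatenation UTR5 + ORF + UTR3 of uniform random
#' sequence; a BED-like sidecar gives the region intervals (0-based
#' half-open), which partition the transcript.
#'
#' @param config a [synth_config()].
#' @param seed optional seed override.
#' @return a list with `records` (`data.frame` of `id`, `seq`) and
#'   `regions` (`data.frame` of `id`, `start`, `end`, `region`).
#' @export
gen_transcripts <- function(config = synth_config(), seed = config$seed) {
  rl <- config$region_lengths[c("UTR5", "ORF", "UTR3")]
  total <- sum(rl)
  with_seed_(derive_seed(seed, 12L), {
    ids <- sprintf("tx-%03d", seq_len(config$n_transcripts))
    seqs <- vapply(seq_len(config$n_transcripts),
                   function(i) random_rna(total), character(1))
    bounds <- cumsum(c(0L, unname(rl)))
    regions <- do.call(rbind, lapply(ids, function(id) {
      data.frame(id = id, start = bounds[1:3], end = bounds[2:4],
                 region = c("UTR5", "ORF", "UTR3"),
                 stringsAsFactors = FALSE)
    }))
    list(records = data.frame(id = ids, seq = seqs,
                              stringsAsFactors = FALSE),
         regions = regions)
  })
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(b)) < rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit],
                     function(x) sample(setdiff(RNA_BASES, x), 1L),
                     character(1), USE.NAMES = FALSE)
  }
  paste(b, collapse = "")
}

#' Generate positive (label 1) chimeras with planted seed complementarity
#'
#' Each positive site carries the reverse complement of its miRNA's seed
#' (nucleotides 2-8) at a random position within a random-sequence site; in
#' `seed_plus_3prime` mode a 6-nt complement to miRNA nt 13-18 is planted
#' 5' of the seed match as well. Site lengths are drawn uniformly so the
#' raw chimera is 60-110 nt; every chimera is then padded to 110 via
#' [pad_chimera()]. Per-base mutation at `config$mutation_rate` is applied
#' to the site after planting, degrading the signal.
#'
#' @param mirnas `data.frame` from [gen_mirnas()].
#' @param config a [synth_config()].
#' @param seed optional seed override.
#' @return a chimera `data.frame` (same columns as
#'   [sample_negative_sites()]) with `label = 1`.
#' @export
gen_positive_chimeras <- function(mirnas, config = synth_config(),
                                  seed = config$seed) {
  n <- config$n_pos
  if (n == 0L) return(empty_chimera_frame())
  with_seed_(derive_seed(seed, 13L), {
    out <- vector("list", n)
    min_site <- 60L - config$mirna_length
    max_site <- CHIMERA_LENGTH - config$mirna_length
    for (i in seq_len(n)) {
      mi <- mirnas[sample.int(nrow(mirnas), 1L), ]
      seed7 <- revcomp_rna(substr(mi$seq, 2L, 8L))
      site_len <- sample(min_site:max_site, 1L)
      site <- random_rna(site_len)
      pos <- sample.int(site_len - 7L + 1L, 1L)
      substr(site, pos, pos + 6L) <- seed7
      if (config$seed_match_mode == "seed_plus_3prime") {
        supp <- revcomp_rna(substr(mi$seq, 13L, 18L))
        # supplementary pairing sits 5' of the seed match on the target
        room <- pos - 6L - 1L
        if (room >= 1L) {
          spos <- sample.int(room, 1L)
          substr(site, spos, spos + 5L) <- supp
        }
      }
      site <- mutate_seq(site, config$mutation_rate)
      raw <- concatenate_chimera(mi$seq, site)
      full <- pad_chimera(raw, mi$seq)
      out[[i]] <- data.frame(
        mirna_id = mi$id, mirna_seq = mi$seq, site_seq = site,
        pad_seq = substr(full, nchar(raw) + 1L, nchar(full)),
        full_seq = full, region = "unknown", transcript_id = NA_character_,
        label = 1L, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate a complete synthetic dataset plus a held-out table
#'
#' Positives come from [gen_positive_chimeras()]; negatives reuse the
#' pseudo-site machinery ([sample_negative_sites()]) over synthetic
#' annotated transcripts, so the same code path that builds real negatives
#' is exercised. The merged table is shuffled and the last `n_heldout`
#' rows split off.
#'
#' @param config a [synth_config()].
#' @return a list with `table` and `heldout` dataset tables
#'   (`chimera_seq`, `label`), plus `mirnas`, `transcripts` and the full
#'   per-chimera frame `chimeras` for provenance.
#' @export
gen_dataset <- function(config = synth_config()) {
  mirnas <- gen_mirnas(config)
  txs <- gen_transcripts(config)
  pos <- gen_positive_chimeras(mirnas, config)
  neg <- sample_negative_sites(txs$records, txs$regions, config$n_neg,
                               mirnas, negative_gen_config(),
                               seed = derive_seed(config$seed, 14L))
  chim <- rbind(pos, neg)
  tab <- data.frame(chimera_seq = chim$full_seq, label = chim$label,
                    stringsAsFactors = FALSE)
  n <- nrow(tab)
  parts <- split_dataset(tab, c(n - config$n_heldout, config$n_heldout, 0L),
                         seed = derive_seed(config$seed, 15L))
  list(table = parts$train, heldout = parts$validation, mirnas = mirnas,
       transcripts = txs, chimeras = chim)
}
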