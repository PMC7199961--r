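#' Concatenate a miRNA and a target site into a raw chimera
#'
#' The chimera is the miRNA (5'->3') followed immediately by the target-site
#' sequence (5'->3'). Chimeras longer than 110 nt cannot be encoded and are
#' rejected, mirroring the dataset-construction rule that drops such reads.
#'
#' @param mirna_seq miRNA sequence (RNA string, typically ~21 nt).
#' @param site_seq target-site sequence (RNA string, non-empty).
#' @return the concatenated chimera string (length <= 110).
#' @export
concatenate_chimera <- function(mirna_seq, site_seq) {
  mirna_seq <- normalize_sequence(mirna_seq)
  site_seq <- normalize_sequence(site_seq)
  if (nchar(mirna_seq) + nchar(site_seq) > CHIMERA_LENGTH) {
    stop(errorCondition(
      sprintf("chimera too long: %d + %d nt exceeds %d",
              nchar(mirna_seq), nchar(site_seq), CHIMERA_LENGTH),
      class = c("mircnn_chimera_too_long", "error", "condition")
    ))
  }
  paste0(mirna_seq, site_seq)
}

# TRUE if any length-4 window of `pad` can base-pair (antiparallel) with any
# length-4 window of `mirna_seq`. Watson-Crick only by default; wobble G:U
# optionally counts as pairing.
pad_pairs_mirna <- function(pad, mirna_seq, wobble = FALSE) {
  if (nchar(pad) < 4L) return(FALSE)
  if (!wobble) {
    rc <- revcomp_rna(mirna_seq)
    if (nchar(rc) < 4L) return(FALSE)
    kmers <- substring(rc, seq_len(nchar(rc) - 3L), seq(4L, nchar(rc)))
    pmers <- substring(pad, seq_len(nchar(pad) - 3L), seq(4L, nchar(pad)))
    return(any(pmers %in% kmers))
  }
  # wobble-aware scan: pad window w pairs with miRNA window v when
  # w[t] pairs v[4 - t + 1] for all t
  pb <- strsplit(pad, "", fixed = TRUE)[[1]]
  mb <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  ok <- can_pair_matrix(allow_wobble = TRUE)
  for (i in seq_len(length(pb) - 3L)) {
    for (j in seq_len(length(mb) - 3L)) {
      w <- pb[i:(i + 3L)]
      v <- mb[j:(j + 3L)]
      if (all(ok[cbind(match(w, RNA_BASES), match(rev(v), RNA_BASES))])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate an anti-complementary random pad
#'
#' Draws i.i.d. uniform bases and rejects whole candidate pads until no
#' window of length 4 or more could base-pair (antiparallel Watson-Crick;
#' optionally counting G:U wobble) with any length-matched window of the
#' miRNA. Padding positive chimeras this way avoids planting spurious
#' binding signal.
#'
#' @param mirna_seq miRNA sequence the pad must not pair with.
#' @param n pad length (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @param wobble should G:U count as pairing during the check? Default
#'   `FALSE` (Watson-Crick only).
#' @param max_tries rejection-sampling cap before failing.
#' @return an RNA string of length `n`.
#' @export
generate_pad <- function(mirna_seq, n, seed = NULL, wobble = FALSE,
                         max_tries = 10000L) {
  stopifnot(n >= 0)
  if (n == 0L) return("")
  mirna_seq <- normalize_sequence(mirna_seq)
  with_seed_(seed, {
    for (i in seq_len(max_tries)) {
      pad <- paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
      if (!pad_pairs_mirna(pad, mirna_seq, wobble = wobble)) return(pad)
    }
    stop(errorCondition(
      sprintf("pad generation failed after %d tries (miRNA %s)",
              max_tries, mirna_seq),
      class = c("mircnn_pad_failure", "error", "condition")
    ))
  })
}

#' Pad a raw chimera to the fixed 110-nt encoding length
#'
#' The raw chimera is preserved as a contiguous prefix; the 3' suffix is
#' filled by [generate_pad()] so the pad cannot base-pair with the miRNA.
#'
#' @param raw raw chimera string (length <= 110).
#' @param mirna_seq the miRNA the pad must avoid pairing with.
#' @inheritParams generate_pad
#' @return a string of length exactly 110.
#' @export
pad_chimera <- function(raw, mirna_seq, seed = NULL, wobble = FALSE) {
  raw <- normalize_sequence(raw)
  if (nchar(raw) > CHIMERA_LENGTH) {
    stop(errorCondition(
      sprintf("chimera too long: %d nt exceeds %d", nchar(raw),
              CHIMERA_LENGTH),
      class = c("mircnn_chimera_too_long", "error", "condition")
    ))
  }
  need <- CHIMERA_LENGTH - nchar(raw)
  if (need == 0L) return(raw)
  paste0(raw, generate_pad(mirna_seq, need, seed = seed, wobble = wobble))
}

#' One-hot encode a 110-nt chimera
#'
#' Each base becomes a length-4 indicator row in the fixed column order
#' A, U, G, C: A = (1,0,0,0), U = (0,1,0,0), G = (0,0,1,0), C = (0,0,0,1).
#'
#' @param full_seq RNA string of length exactly 110.
#' @return an integer 110 x 4 matrix with one 1 per row; columns named
#'   A, U, G, C.
#' @seealso [decode_one_hot()]
#' @export
encode_one_hot <- function(full_seq) {
  full_seq <- normalize_sequence(full_seq)
  if (nchar(full_seq) != CHIMERA_LENGTH) {
    stop(sprintf("sequence must be exactly %d nt, got %d", CHIMERA_LENGTH,
                 nchar(full_seq)), call. = FALSE)
  }
  idx <- match(strsplit(full_seq, "", fixed = TRUE)[[1]], RNA_BASES)
  m <- matrix(0L, CHIMERA_LENGTH, 4L, dimnames = list(NULL, RNA_BASES))
  m[cbind(seq_len(CHIMERA_LENGTH), idx)] <- 1L
  m
}

#' Decode a one-hot matrix back to its RNA string
#'
#' @param mat a 110 x 4 one-hot matrix in A, U, G, C column order.
#' @return the RNA string.
#' @export
decode_one_hot <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  if (!all(rowSums(mat) == 1L) || !all(mat %in% c(0L, 1L))) {
    stop("not a one-hot matrix: each row must have a single 1", call. = FALSE)
  }
  paste(RNA_BASES[max.col(mat)], collapse = "")
}

#' Encode a dataset table as a batch of one-hot tensors
#'
#' @param table validated dataset table ([validate_dataset_table()]).
#' @return a list with `data`, an n x 110 x 4 array, and `labels`, an
#'   integer vector of 0/1.
#' @export
encode_batch <- function(table) {
  table <- validate_dataset_table(table)
  n <- nrow(table)
  arr <- array(0, dim = c(n, CHIMERA_LENGTH, 4L))
  if (n > 0L) {
    chars <- strsplit(table$chimera_seq, "", fixed = TRUE)
    idx <- match(unlist(chars, use.names = FALSE), RNA_BASES)
    pos <- rep(seq_len(CHIMERA_LENGTH), times = n)
    smp <- rep(seq_len(n), each = CHIMERA_LENGTH)
    arr[cbind(smp, pos, idx)] <- 1
  }
  list(data = arr, labels = as.integer(table$label))
}

#' Configuration for pseudo-negative chimera generation
#'
#' @param region_proportions integer ratio of 3'UTR : 5'UTR : ORF draws;
#'   default `c(7, 2, 1)`.
#' @param chimera_length fixed chimera length, 110.
#' @param pad_negatives if `TRUE`, negative sites are shortened (drawn with
#'   the same length distribution as positives) and padded like positives,
#'   removing the pad-presence confound between the classes; default
#'   `FALSE`, matching the standard construction in which negatives always
#'   fill the full 110 nt.
#' @param seed optional integer seed.
#' @return a list of class `negative_gen_config`.
#' @export
negative_gen_config <- function(region_proportions = c(UTR3 = 7L, UTR5 = 2L,
                                                       ORF = 1L),
                                chimera_length = CHIMERA_LENGTH,
                                pad_negatives = FALSE, seed = NULL) {
  stopifnot(length(region_proportions) == 3L, all(region_proportions > 0))
  if (is.null(names(region_proportions))) {
    names(region_proportions) <- c("UTR3", "UTR5", "ORF")
  }
  structure(list(region_proportions = region_proportions,
                 chimera_length = as.integer(chimera_length),
                 pad_negatives = isTRUE(pad_negatives), seed = seed),
            class = "negative_gen_config")
}

# Largest-remainder apportionment of n draws over integer proportions.
apportion <- function(n, proportions) {
  quota <- n * proportions / sum(proportions)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_idx <- order(quota - counts, decreasing = TRUE)
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Sample pseudo-negative miRNA:site chimeras from annotated transcripts
#'
#' Draws pseudo target sites at random from the 3'UTR, 5'UTR and ORF of the
#' supplied transcripts in a 7:2:1 proportion (largest-remainder
#' apportionment when n is not divisible), pairing each with a random miRNA
#' while avoiding any (miRNA, gene) combination in `forbidden_pairs` (known
#' true interactions must not become negatives). Each chimera fills the full
#' 110 nt: the site length is 110 minus the miRNA length and the pad is
#' empty, unless `config$pad_negatives` is set.
#'
#' @param transcripts `data.frame` with columns `id`, `seq`.
#' @param regions BED-like sidecar `data.frame` with columns `id`
#'   (transcript id), `start`, `end` (0-based half-open) and `region`
#'   (one of `UTR5`, `ORF`, `UTR3`).
#' @param n number of negatives to generate.
#' @param mirnas `data.frame` with columns `id`, `seq`.
#' @param config a [negative_gen_config()].
#' @param forbidden_pairs optional 2-column `data.frame`/matrix of
#'   (mirna_id, transcript_id) pairs that must not be produced.
#' @param seed optional integer seed (overrides `config$seed`).
#' @return a `data.frame` of chimeras with columns `mirna_id`, `mirna_seq`,
#'   `site_seq`, `pad_seq`, `full_seq`, `region`, `transcript_id`, `label`
#'   (all 0).
#' @export
sample_negative_sites <- function(transcripts, regions, n, mirnas,
                                  config = negative_gen_config(),
                                  forbidden_pairs = NULL, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0L) {
    return(empty_chimera_frame())
  }
  if (is.null(seed)) seed <- config$seed
  forb <- character()
  if (!is.null(forbidden_pairs) && NROW(forbidden_pairs) > 0L) {
    forb <- paste(forbidden_pairs[[1]], forbidden_pairs[[2]], sep = "\r")
  }
  counts <- apportion(n, config$region_proportions)
  with_seed_(seed, {
    out <- vector("list", n)
    k <- 0L
    for (reg in names(counts)) {
      reg_rows <- regions[regions$region == reg, , drop = FALSE]
      if (nrow(reg_rows) == 0L && counts[[reg]] > 0L) {
        stop("no transcript carries a ", reg, " annotation", call. = FALSE)
      }
      for (i in seq_len(counts[[reg]])) {
        drawn <- FALSE
        for (try in seq_len(1000L)) {
          mi <- mirnas[sample.int(nrow(mirnas), 1L), ]
          site_len <- config$chimera_length - nchar(mi$seq)
          if (config$pad_negatives) {
            site_len <- sample(seq(39L, site_len), 1L)
          }
          ri <- reg_rows[sample.int(nrow(reg_rows), 1L), ]
          if (ri$end - ri$start < site_len) next
          if (paste(mi$id, ri$id, sep = "\r") %in% forb) next
          start0 <- ri$start + sample.int(ri$end - ri$start - site_len + 1L,
                                          1L) - 1L
          tr <- transcripts[transcripts$id == ri$id, ]
          site <- substr(tr$seq[1], start0 + 1L, start0 + site_len)
          raw <- concatenate_chimera(mi$seq, site)
          full <- if (nchar(raw) < config$chimera_length) {
            pad_chimera(raw, mi$seq)
          } else raw
          k <- k + 1L
          out[[k]] <- data.frame(
            mirna_id = mi$id, mirna_seq = mi$seq, site_seq = site,
            pad_seq = substr(full, nchar(raw) + 1L, nchar(full)),
            full_seq = full, region = reg, transcript_id = ri$id,
            label = 0L, stringsAsFactors = FALSE)
          drawn <- TRUE
          break
        }
        if (!drawn) {
          stop("could not place a pseudo site in region ", reg,
               " after 1000 tries", call. = FALSE)
        }
      }
    }
    res <- do.call(rbind, out[seq_len(k)])
    rownames(res) <- NULL
    res
  })
}

empty_chimera_frame <- function() {
  data.frame(mirna_id = character(), mirna_seq = character(),
             site_seq = character(), pad_seq = character(),
             full_seq = character(), region = character(),
             transcript_id = character(), label = integer(),
             stringsAsFactors = FALSE)
}

#' Split a dataset into train / validation / test partitions
#'
#' The partition is disjoint, exhaustive and reproducible under the seed.
#'
#' @param table dataset table.
#' @param sizes integer vector `c(train, validation, test)` summing to
#'   `nrow(table)`.
#' @param seed optional integer seed.
#' @return a named list of three dataset tables (`train`, `validation`,
#'   `test`).
#' @export
split_dataset <- function(table, sizes, seed = NULL) {
  table <- validate_dataset_table(table)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0) || sum(sizes) != nrow(table)) {
    stop("sizes must be three non-negative counts summing to nrow(table)",
         call. = FALSE)
  }
  with_seed_(seed, {
    # canonicalize row order first so the partition's membership depends
    # only on the table's contents and the seed, not on input row order
    canon <- order(table$chimera_seq, table$label)
    perm <- canon[sample.int(nrow(table))]
    stops <- cumsum(sizes)
    starts <- c(1L, stops[-3L] + 1L)
    out <- lapply(1:3, function(i) {
      rows <- if (sizes[i] == 0L) integer() else perm[starts[i]:stops[i]]
      tab <- table[rows, , drop = FALSE]
      rownames(tab) <- NULL
      tab
    })
    names(out) <- c("train", "validation", "test")
    out
  })
}

#' Split a dataset into k folds of near-equal size
#'
#' Folds are disjoint, exhaustive and differ in size by at most one row.
#' With `stratify = TRUE` rows are grouped by label before cyclic
#' assignment, so each fold also carries a near-identical class balance.
#'
#' @param table dataset table.
#' @param k number of folds (>= 2, <= `nrow(table)`).
#' @param seed optional integer seed.
#' @param stratify balance labels across folds? Default `FALSE` (plain
#'   random folds).
#' @return a list of `k` dataset tables.
#' @export
kfold_split <- function(table, k, seed = NULL, stratify = FALSE) {
  table <- validate_dataset_table(table)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(table)) stop("k exceeds the number of rows", call. = FALSE)
  with_seed_(seed, {
    if (stratify) {
      # shuffle, then stable-sort by label; cyclic assignment below then
      # spreads each class evenly over the folds
      shuf <- sample.int(nrow(table))
      perm <- shuf[order(table$label[shuf])]
    } else {
      perm <- sample.int(nrow(table))
    }
    fold_id <- rep_len(seq_len(k), nrow(table))  # cyclic over permuted rows
    lapply(seq_len(k), function(f) {
      tab <- table[perm[fold_id == f], , drop = FALSE]
      rownames(tab) <- NULL
      tab
    })
  })
}
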