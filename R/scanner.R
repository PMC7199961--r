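#' Enumerate candidate target sites along a transcript
#'
#' Windows have length `110 - nchar(miRNA)` so that each candidate chimera
#' is exactly 110 nt and needs no pad, matching how full-length negative
#' chimeras are built. Windows start at offsets 0, step, 2*step, ...; a
#' final window flush with the transcript end is added when the stride does
#' not land there. Transcripts no longer than one window yield a single
#' candidate covering the whole transcript.
#'
#' @param mirna single-row `data.frame` (`id`, `seq`) or list with those
#'   fields.
#' @param transcript single-row `data.frame`/list with `id`, `seq`.
#' @param step window stride in nt (>= 1), default 5.
#' @param min_transcript minimum transcript length accepted, default 8.
#' @return a `data.frame` with `transcript_id`, `start`, `end` (0-based
#'   half-open) and `site_seq`.
#' @export
enumerate_candidates <- function(mirna, transcript, step = 5L,
                                 min_transcript = 8L) {
  stopifnot(step >= 1L)
  tseq <- normalize_sequence(transcript$seq[[1]])
  mseq <- normalize_sequence(mirna$seq[[1]])
  L <- nchar(tseq)
  if (L < min_transcript) {
    stop(sprintf("transcript %s too short (%d nt < %d)",
                 transcript$id[[1]], L, min_transcript), call. = FALSE)
  }
  w <- CHIMERA_LENGTH - nchar(mseq)
  if (w < 1L) stop("miRNA too long for any target window", call. = FALSE)
  if (L <= w) {
    starts <- 0L
    w_eff <- L
  } else {
    starts <- as.integer(seq(0L, L - w, by = as.integer(step)))
    if (starts[length(starts)] != L - w) starts <- c(starts, L - w)
    w_eff <- w
  }
  data.frame(
    transcript_id = transcript$id[[1]],
    start = starts,
    end = starts + w_eff,
    site_seq = substring(tseq, starts + 1L, starts + w_eff),
    stringsAsFactors = FALSE)
}

#' Scan a full-length transcript for miRNA targeting
#'
#' The pipeline: enumerate candidate windows, compute the miRNA:site duplex
#' MFE for each, keep only candidates at or below `mfe_threshold`
#' (default -20 kcal/mol), build the 110-nt chimera for each survivor
#' (padding when the transcript is shorter than a full window), score with
#' the trained CNN, and aggregate by the maximum site score. The
#' transcript-level call is `TRUE` when that maximum is strictly greater
#' than `call_threshold`; with no surviving candidate the maximum is 0 and
#' the call `FALSE`.
#'
#' @param model a trained `mircnn_model`.
#' @param mirna,transcript single records with `id` and `seq`.
#' @param mfe_threshold duplex-stability filter, kcal/mol; default -20.
#' @param call_threshold decision threshold on the max score; default 0.5.
#' @param step window stride, default 5.
#' @param seed optional seed (only used when a short candidate needs a
#'   random pad).
#' @param params duplex parameter set, default [default_duplex_params()].
#' @return a list of class `scan_result`: `mirna_id`, `transcript_id`,
#'   `sites` (scored survivors: start, end, site_seq, mfe, score),
#'   `n_candidates`, `max_score`, `call`.
#' @export
scan_transcript <- function(model, mirna, transcript, mfe_threshold = -20,
                            call_threshold = 0.5, step = 5L, seed = NULL,
                            params = default_duplex_params()) {
  stopifnot(inherits(model, "mircnn_model"))
  cands <- enumerate_candidates(mirna, transcript, step = step)
  mseq <- normalize_sequence(mirna$seq[[1]])
  cands$mfe <- vapply(cands$site_seq,
                      function(s) duplex_mfe(mseq, s, params)$mfe,
                      numeric(1), USE.NAMES = FALSE)
  surv <- filter_candidates(cands, mfe_threshold)
  if (nrow(surv) == 0L) {
    return(structure(list(mirna_id = mirna$id[[1]],
                          transcript_id = transcript$id[[1]],
                          sites = cbind(surv, score = numeric(0)),
                          n_candidates = nrow(cands),
                          max_score = 0, call = FALSE),
                     class = "scan_result"))
  }
  full <- vapply(seq_len(nrow(surv)), function(r) {
    raw <- concatenate_chimera(mseq, surv$site_seq[r])
    if (nchar(raw) < CHIMERA_LENGTH) {
      pad_chimera(raw, mseq, seed = derive_seed(seed, r))
    } else raw
  }, character(1))
  batch <- encode_batch(data.frame(chimera_seq = full,
                                   label = 0L,  # placeholder, unused
                                   stringsAsFactors = FALSE))
  surv$score <- predict(model, batch)
  max_score <- max(surv$score)
  structure(list(mirna_id = mirna$id[[1]],
                 transcript_id = transcript$id[[1]], sites = surv,
                 n_candidates = nrow(cands), max_score = max_score,
                 call = max_score > call_threshold),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: %d candidates, %d past the energy filter, max score %.3f -> %s\n",
    x$mirna_id, x$transcript_id, x$n_candidates, nrow(x$sites),
    x$max_score, if (x$call) "TARGET" else "no target"))
  invisible(x)
}

#' Scan every miRNA against every transcript
#'
#' One row per (miRNA, transcript) pair, in input order. A failing pair is
#' reported as a warning and skipped rather than aborting the batch.
#'
#' @inheritParams scan_transcript
#' @param mirnas,transcripts `data.frame`s with columns `id`, `seq`.
#' @return a `data.frame` with `mirna_id`, `transcript_id`,
#'   `n_candidates`, `n_survivors`, `best_site_start`, `best_site_end`,
#'   `best_mfe`, `max_score`, `call`.
#' @export
scan_many <- function(model, mirnas, transcripts, mfe_threshold = -20,
                      call_threshold = 0.5, step = 5L, seed = NULL,
                      params = default_duplex_params()) {
  stopifnot(nrow(mirnas) > 0L)
  rows <- list()
  k <- 0L
  for (mi in seq_len(nrow(mirnas))) {
    for (ti in seq_len(NROW(transcripts))) {
      res <- tryCatch(
        scan_transcript(model, mirnas[mi, ], transcripts[ti, ],
                        mfe_threshold = mfe_threshold,
                        call_threshold = call_threshold, step = step,
                        seed = derive_seed(seed, mi * 10007L + ti),
                        params = params),
        error = function(e) {
          warning(sprintf("skipping %s vs %s: %s", mirnas$id[mi],
                          transcripts$id[ti], conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (is.null(res)) next
      k <- k + 1L
      best <- if (nrow(res$sites)) which.max(res$sites$score) else NA
      rows[[k]] <- data.frame(
        mirna_id = res$mirna_id, transcript_id = res$transcript_id,
        n_candidates = res$n_candidates, n_survivors = nrow(res$sites),
        best_site_start = if (is.na(best[1])) NA_integer_ else
          res$sites$start[best],
        best_site_end = if (is.na(best[1])) NA_integer_ else
          res$sites$end[best],
        best_mfe = if (is.na(best[1])) NA_real_ else res$sites$mfe[best],
        max_score = res$max_score, call = res$call,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      n_candidates = integer(), n_survivors = integer(),
                      best_site_start = integer(),
                      best_site_end = integer(), best_mfe = numeric(),
                      max_score = numeric(), call = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
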