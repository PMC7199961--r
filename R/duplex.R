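# Intermolecular miRNA:site hybridization energy.
#
# Model: the two strands form a single antiparallel duplex -- a chain of
# canonical base pairs (A-U, G-C, optionally G-U) in which consecutive pairs
# are either directly stacked (nearest-neighbor stack energy) or separated
# by a bulge/internal loop penalized linearly in its total unpaired length.
# No intramolecular pairs, no multiloops, no dangling ends. The minimum
# free energy over all such structures (plus a single duplex initiation
# term) is reported; structures that never go below zero are summarized as
# "no stable duplex" (MFE 0, empty pairing).

# 4x4 logical matrix over A,U,G,C: which bases can pair.
can_pair_matrix <- function(allow_wobble = TRUE) {
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  if (allow_wobble) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

.duplex_cache <- new.env(parent = emptyenv())

#' Load the nearest-neighbor duplex parameter set
#'
#' Reads the versioned stacking/loop parameter table shipped with the
#' package (or a user-supplied file in the same format) and expands it into
#' fast lookup structures. Stack energies are indexed as
#' `stack[x1, x2, y1, y2]` for the stack of pair (x1:y1) on pair (x2:y2),
#' with x1, x2 consecutive 5'->3' on one strand and y1, y2 the partners on
#' the other; the strand-swap symmetry is applied automatically.
#'
#' @param allow_wobble allow G:U pairs in duplexes? Default `TRUE`
#'   (standard for RNA:RNA hybridization; note the pad-generation rule in
#'   [generate_pad()] is Watson-Crick only by default, a separate choice).
#' @param file optional path to an alternative parameter TSV.
#' @return a list of class `nn_parameter_set` with elements `stack`
#'   (4x4x4x4 numeric array, `NA` where undefined), `init`, `loop_base`,
#'   `loop_per_nt`, `can_pair`, `allow_wobble`, `version`.
#' @export
default_duplex_params <- function(allow_wobble = TRUE, file = NULL) {
  key <- paste0(ifelse(allow_wobble, "w", "nw"), "|",
                ifelse(is.null(file), "builtin", file))
  if (!is.null(.duplex_cache[[key]])) return(.duplex_cache[[key]])
  if (is.null(file)) {
    file <- system.file("extdata", "duplex_nn_params_v1.tsv",
                        package = "mircnn", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  scalars <- tab[tab$kind == "scalar", ]
  sc <- stats::setNames(scalars$value, scalars$name)
  stack <- array(NA_real_, dim = c(4, 4, 4, 4),
                 dimnames = list(RNA_BASES, RNA_BASES, RNA_BASES, RNA_BASES))
  for (r in which(tab$kind == "stack")) {
    nm <- strsplit(tab$name[r], "/", fixed = TRUE)[[1]]
    top <- strsplit(nm[1], "")[[1]]; bot <- strsplit(nm[2], "")[[1]]
    e <- tab$value[r]
    stack[top[1], top[2], bot[1], bot[2]] <- e
    stack[bot[2], bot[1], top[2], top[1]] <- e  # strand swap
  }
  cp <- can_pair_matrix(allow_wobble)
  if (!allow_wobble) {
    # drop any stack touching a wobble pair
    for (i1 in 1:4) for (i2 in 1:4) for (j1 in 1:4) for (j2 in 1:4) {
      if (!cp[i1, j1] || !cp[i2, j2]) stack[i1, i2, j1, j2] <- NA_real_
    }
  }
  params <- structure(
    list(stack = stack, init = unname(sc["duplex_init"]),
         loop_base = unname(sc["loop_base"]),
         loop_per_nt = unname(sc["loop_per_nt"]),
         can_pair = cp, allow_wobble = allow_wobble,
         version = "nn-v1"),
    class = "nn_parameter_set")
  .duplex_cache[[key]] <- params
  params
}

#' Minimum free energy of an intermolecular miRNA:site duplex
#'
#' Dynamic program over all antiparallel duplex structures: chains of
#' canonical pairs connected by stacks or by bulges/internal loops with a
#' linear size penalty, plus one initiation term. Returns the most stable
#' structure; when nothing reaches a negative energy the result is an MFE
#' of 0 with empty pairing.
#'
#' @param mirna_seq RNA string (length >= 2).
#' @param site_seq RNA string (length >= 2).
#' @param params a [default_duplex_params()] parameter set.
#' @return a list of class `duplex_result`: `mfe` (kcal/mol, <= 0), `pairs`
#'   (2-column matrix of 1-based paired positions, miRNA then site),
#'   `mirna_range`, `site_range`, `structure` (dot-bracket-like
#'   `"...((( & )))..."` two-strand string), `params_version`.
#' @examples
#' duplex_mfe("ACGACGACG", "CGUCGUCGU")$mfe
#' @export
duplex_mfe <- function(mirna_seq, site_seq,
                       params = default_duplex_params()) {
  mirna_seq <- normalize_sequence(mirna_seq)
  site_seq <- normalize_sequence(site_seq)
  x <- match(strsplit(mirna_seq, "", fixed = TRUE)[[1]], RNA_BASES)
  y <- match(strsplit(site_seq, "", fixed = TRUE)[[1]], RNA_BASES)
  n <- length(x); m <- length(y)
  if (n < 2L || m < 2L) {
    stop("both sequences must be at least 2 nt", call. = FALSE)
  }
  cp <- unname(params$can_pair)
  init <- params$init; lb <- params$loop_base; c1 <- params$loop_per_nt

  E <- matrix(Inf, n, m)
  type <- matrix(0L, n, m)            # 0 start, 1 stack, 2 loop
  predI <- matrix(0L, n, m); predJ <- matrix(0L, n, m)
  # S[j]: min over rows < current of F(i',j') for j' >= j (sentinel m+1)
  S <- rep(Inf, m + 1L); SaI <- integer(m + 1L); SaJ <- integer(m + 1L)
  jv <- seq_len(m)

  for (i in seq_len(n)) {
    pairable <- cp[x[i], y]
    best <- rep(Inf, m); ty <- integer(m)
    best[pairable] <- init
    if (i > 1L) {
      se <- rep(NA_real_, m)
      se[jv < m] <- params$stack[cbind(x[i - 1L], x[i], y[jv[jv < m] + 1L],
                                       y[jv[jv < m]])]
      stack_cand <- c(E[i - 1L, -1L], Inf) + ifelse(is.na(se), Inf, se)
      upd <- pairable & stack_cand < best
      best[upd] <- stack_cand[upd]; ty[upd] <- 1L
    }
    loop_cand <- lb + c1 * (i - jv - 2) + S[jv + 1L]
    upd <- pairable & loop_cand < best
    best[upd] <- loop_cand[upd]; ty[upd] <- 2L
    E[i, ] <- best
    type[i, ] <- ty
    predI[i, ty == 1L] <- i - 1L
    predJ[i, ty == 1L] <- jv[ty == 1L] + 1L
    predI[i, ty == 2L] <- SaI[jv[ty == 2L] + 1L]
    predJ[i, ty == 2L] <- SaJ[jv[ty == 2L] + 1L]
    # fold row i into the prefix-min structure S
    Fi <- E[i, ] - c1 * (i - jv)
    run <- Inf; runj <- 0L
    for (j in m:1) {
      if (Fi[j] < run) { run <- Fi[j]; runj <- j }
      if (run < S[j]) { S[j] <- run; SaI[j] <- i; SaJ[j] <- runj }
    }
  }

  best_e <- min(E)
  if (!is.finite(best_e) || best_e >= 0) {
    return(structure(list(
      mfe = 0, pairs = matrix(integer(), 0, 2,
                              dimnames = list(NULL, c("i", "j"))),
      mirna_range = c(NA_integer_, NA_integer_),
      site_range = c(NA_integer_, NA_integer_),
      structure = "", params_version = params$version),
      class = "duplex_result"))
  }
  idx <- which(E == best_e, arr.ind = TRUE)[1, ]
  pi_ <- idx[1]; pj <- idx[2]
  pairs <- matrix(integer(), 0, 2)
  repeat {
    pairs <- rbind(c(pi_, pj), pairs)
    if (type[pi_, pj] == 0L) break
    ni <- predI[pi_, pj]; nj <- predJ[pi_, pj]
    pi_ <- ni; pj <- nj
  }
  colnames(pairs) <- c("i", "j")
  ir <- range(pairs[, 1]); jr <- range(pairs[, 2])
  db1 <- rep(".", ir[2] - ir[1] + 1L); db2 <- rep(".", jr[2] - jr[1] + 1L)
  db1[pairs[, 1] - ir[1] + 1L] <- "("
  db2[pairs[, 2] - jr[1] + 1L] <- ")"
  structure(list(
    mfe = best_e, pairs = pairs, mirna_range = ir, site_range = jr,
    structure = paste0(paste(db1, collapse = ""), "&",
                       paste(db2, collapse = "")),
    params_version = params$version),
    class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("duplex MFE: %.2f kcal/mol", x$mfe))
  if (nrow(x$pairs) > 0) {
    cat(sprintf("  (%d pairs, miRNA %d-%d : site %d-%d)\n  %s\n",
                nrow(x$pairs), x$mirna_range[1], x$mirna_range[2],
                x$site_range[1], x$site_range[2], x$structure))
  } else cat("  (no stable duplex)\n")
  invisible(x)
}

#' Filter candidate sites on duplex stability
#'
#' Keeps exactly the candidates whose minimum free energy is at or below
#' the threshold (default -20 kcal/mol), preserving input order. Long
#' transcripts offer the classifier many chances at a false positive; the
#' energy filter removes sites that cannot form a stable hybrid before any
#' scoring happens.
#'
#' @param candidates `data.frame` with an `mfe` column (kcal/mol).
#' @param threshold keep rows with `mfe <= threshold`; default -20.
#' @return the filtered `data.frame`, order preserved.
#' @export
filter_candidates <- function(candidates, threshold = -20) {
  stopifnot(is.data.frame(candidates), "mfe" %in% names(candidates),
            is.numeric(threshold), !is.na(threshold))
  out <- candidates[candidates$mfe <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
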