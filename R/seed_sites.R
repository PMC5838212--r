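# Canonical miRNA seed-site scanning on 3'-UTRs.
#
# Site taxonomy (UTR written 5'->3'; miRNA pairs antiparallel, so miRNA
# position 1 faces the 3'-most UTR position of the site):
#   6mer    : reverse complement of miRNA nt 2-7
#   7mer-m8 : reverse complement of miRNA nt 2-8
#   7mer-A1 : 6mer followed by an A opposite miRNA position 1
#   8mer    : 7mer-m8 followed by the A1 adenosine
# A longer type subsumes any shorter-type match whose interval it contains.

revcomp_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

normalize_nt <- function(s, what) {
  s <- chartr("u", "t", tolower(s))
  s <- toupper(s)
  bad <- gsub("[ACGT]", "", s)
  if (nzchar(bad)) {
    stop(sprintf("ambiguous nucleotide code(s) in %s: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  }
  s
}

# The four site patterns for one mature miRNA sequence (5'->3').
seed_patterns <- function(mirna) {
  mirna <- normalize_nt(mirna, "miRNA")
  if (nchar(mirna) < 8) stop("mature miRNA sequence must be >= 8 nt")
  p6 <- revcomp_dna(substr(mirna, 2, 7))
  p7m8 <- revcomp_dna(substr(mirna, 2, 8))
  c("6mer" = p6, "7mer-A1" = paste0(p6, "A"),
    "7mer-m8" = p7m8, "8mer" = paste0(p7m8, "A"))
}

# All (possibly overlapping) start positions of fixed pattern `pat`, 0-based.
find_all <- function(utr, pat) {
  hits <- gregexpr(paste0("(?=", pat, ")"), utr, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

#' Locate canonical miRNA seed-match sites on a 3'-UTR
#'
#' Scans the sense strand of a 3'-UTR (5'->3') for exact matches to the
#' reverse complement of the miRNA seed region, reporting 6mer, 7mer-A1,
#' 7mer-m8, and 8mer sites. A match whose interval is contained in a
#' longer-type match at the same locus is subsumed and not reported.
#' U and T are treated as equivalent; ambiguous nucleotide codes are an
#' error.
#'
#' @param utr UTR nucleotide sequence (character scalar, A/C/G/T/U).
#' @param mirna mature miRNA sequence, 5'->3', length >= 8.
#' @param mirna_id id reported in the output.
#' @param utr_id id reported in the output.
#' @return data.frame with columns `utr_id`, `mirna_id`, `start`, `end`
#'   (0-based half-open UTR coordinates), `site_type`, ordered by `start`.
#' @export
seed_sites <- function(utr, mirna, mirna_id = "mirna", utr_id = "utr") {
  utr <- normalize_nt(utr, "UTR")
  pats <- seed_patterns(mirna)
  cand <- do.call(rbind, lapply(names(pats), function(ty) {
    st <- find_all(utr, pats[[ty]])
    if (!length(st)) return(NULL)
    data.frame(start = st, end = st + nchar(pats[[ty]]),
               site_type = ty, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0) {
    return(empty_sites())
  }
  len <- cand$end - cand$start
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    !any(len > len[i] &
         cand$start <= cand$start[i] & cand$end >= cand$end[i])
  }, logical(1))
  out <- cand[keep, , drop = FALSE]
  out <- data.frame(utr_id = utr_id, mirna_id = mirna_id, out,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(utr_id = character(0), mirna_id = character(0),
             start = integer(0), end = integer(0),
             site_type = character(0), stringsAsFactors = FALSE)
}

# transversion maps used for deterministic disruptive substitutions
TRANSVERSION_MAPS <- c("CATG", "TGCA")  # A<->C,G<->T then A<->T,C<->G

# 0-based interval of the 6mer core (complement of miRNA nt 2-7) within a
# site of the given type.
site_core <- function(start, end, site_type) {
  switch(site_type,
    "6mer" = c(start, start + 6L),
    "7mer-A1" = c(start, start + 6L),
    "7mer-m8" = c(start + 1L, start + 7L),
    "8mer" = c(start + 1L, start + 7L),
    stop("unknown site type: ", site_type)
  )
}

#' Disrupt a seed site by point substitution
#'
#' Substitutes `n_mut` positions inside the site with transversions chosen
#' so that re-scanning the mutated UTR finds no site of any type for the
#' same miRNA overlapping the original site interval. Positions are chosen
#' deterministically from the center of the seed-pairing core outward
#' (supply `seed` to randomize the choice instead); sequence length is
#' always preserved.
#'
#' @param utr UTR sequence the site was found on.
#' @param site one row of a [seed_sites()] table (or any list with `start`,
#'   `end`, `site_type`).
#' @param mirna the mature miRNA sequence, used to verify abolition.
#' @param n_mut number of positions to substitute (1..site length).
#' @param seed optional RNG seed for randomized position choice.
#' @return The mutated UTR sequence; mutated 0-based positions are attached
#'   as attribute `"mutated_positions"`.
#' @export
disrupt_site <- function(utr, site, mirna, n_mut = 2, seed = NULL) {
  utr <- normalize_nt(utr, "UTR")
  start <- as.integer(site$start)
  end <- as.integer(site$end)
  width <- end - start
  if (start < 0 || end > nchar(utr)) stop("site lies outside the UTR")
  if (n_mut < 1 || n_mut > width) {
    stop("n_mut must be between 1 and the site length")
  }
  core <- site_core(start, end, site$site_type)
  core_pos <- seq(core[1], core[2] - 1L)
  rest <- setdiff(seq(start, end - 1L), core_pos)
  order_center <- function(p) {
    if (!length(p)) return(integer(0))
    p[order(abs(p - mean(range(p))), p)]
  }
  ordered <- c(order_center(core_pos), order_center(rest))
  if (!is.null(seed)) {
    ordered <- with_seed(seed, sample(ordered))
  }

  pick <- utils::combn(seq_along(ordered), n_mut, simplify = FALSE)
  # prefer the centre-most combination; combn on the ordered index vector
  # already enumerates in that preference order
  for (map in TRANSVERSION_MAPS) {
    for (idx in pick) {
      pos <- ordered[idx]
      mut <- utr
      for (p in pos) {
        b <- substr(mut, p + 1, p + 1)
        substr(mut, p + 1, p + 1) <- chartr("ACGT", map, b)
      }
      rescan <- seed_sites(mut, mirna)
      overlapping <- rescan$start < end & rescan$end > start
      if (!any(overlapping)) {
        return(structure(mut, mutated_positions = sort(pos)))
      }
    }
  }
  stop("unable to abolish the site with the requested number of mutations")
}

#' Scan every UTR against every miRNA
#'
#' @param utrs named character vector of UTR sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param mirnas named character vector of mature miRNA sequences.
#' @return List with `sites` (concatenated [seed_sites()] records) and
#'   `counts` (data.frame `utr_id`, `mirna_id`, `n_sites` for every pair).
#' @export
crossmatch <- function(utrs, mirnas) {
  if (inherits(utrs, "XStringSet")) {
    utrs <- setNames(as.character(utrs), names(utrs))
  }
  if (length(utrs) == 0 || length(mirnas) == 0) {
    stop("crossmatch needs nonempty UTR and miRNA sets")
  }
  if (is.null(names(utrs)) || is.null(names(mirnas))) {
    stop("UTRs and miRNAs must be named")
  }
  if (anyDuplicated(names(utrs))) stop("duplicate UTR ids")
  if (anyDuplicated(names(mirnas))) stop("duplicate miRNA ids")
  sites <- list()
  counts <- list()
  for (u in names(utrs)) {
    for (m in names(mirnas)) {
      s <- seed_sites(utrs[[u]], mirnas[[m]], mirna_id = m, utr_id = u)
      sites[[paste(u, m)]] <- s
      counts[[paste(u, m)]] <- data.frame(
        utr_id = u, mirna_id = m, n_sites = nrow(s),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    sites = {
      x <- do.call(rbind, c(list(empty_sites()), sites))
      rownames(x) <- NULL
      x
    },
    counts = {
      x <- do.call(rbind, counts)
      rownames(x) <- NULL
      x
    }
  )
}

#' Simulate a 3'-UTR with planted seed sites
#'
#' Writes exact seed-match substrings into a random background sequence at
#' the requested positions, then screens the rest of the sequence so that no
#' accidental site of any canonical type exists for any planted miRNA:
#' accidental matches are patched by transversion at a position outside the
#' planted intervals, iterating until the scan is clean.
#'
#' @param length UTR length, nt.
#' @param planted data.frame (or list of lists) with columns `mirna`
#'   (mature sequence), `position` (0-based site start), `site_type`;
#'   optionally `mirna_id`. Sites must not overlap.
#' @param seed RNG seed.
#' @return List with `sequence` and `truth` (data.frame `mirna_id`,
#'   `start`, `end`, `site_type`).
#' @export
simulate_utr <- function(length, planted = NULL, seed = 1) {
  planted <- if (is.null(planted)) {
    data.frame(mirna = character(0), position = integer(0),
               site_type = character(0), stringsAsFactors = FALSE)
  } else if (!is.data.frame(planted)) {
    do.call(rbind, lapply(planted, as.data.frame,
                          stringsAsFactors = FALSE))
  } else {
    planted
  }
  if (is.null(planted$mirna_id)) {
    planted$mirna_id <- if (nrow(planted)) {
      sprintf("mirna%d", seq_len(nrow(planted)))
    } else {
      character(0)
    }
  }

  site_str <- character(nrow(planted))
  ends <- integer(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    pats <- seed_patterns(planted$mirna[i])
    if (!planted$site_type[i] %in% names(pats)) {
      stop("unknown site type: ", planted$site_type[i])
    }
    site_str[i] <- pats[[planted$site_type[i]]]
    ends[i] <- planted$position[i] + nchar(site_str[i])
    if (planted$position[i] < 0 || ends[i] > length) {
      stop("planted site outside sequence bounds")
    }
  }
  if (nrow(planted) > 1) {
    o <- order(planted$position)
    if (any(planted$position[o][-1] < ends[o][-nrow(planted)])) {
      stop("overlapping planted sites")
    }
  }
  in_planted <- rep(FALSE, length)
  for (i in seq_len(nrow(planted))) {
    in_planted[seq(planted$position[i] + 1, ends[i])] <- TRUE
  }

  with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    for (i in seq_len(nrow(planted))) {
      chars[seq(planted$position[i] + 1, ends[i])] <-
        strsplit(site_str[i], "")[[1]]
    }
    seqn <- paste(chars, collapse = "")

    planted_iv <- cbind(planted$position, ends)
    is_planted_site <- function(s) {
      any(planted_iv[, 1] <= s$start & planted_iv[, 2] >= s$end)
    }
    for (iter in seq_len(200)) {
      accidental <- NULL
      for (i in seq_len(nrow(planted))) {
        sc <- seed_sites(seqn, planted$mirna[i])
        for (j in seq_len(nrow(sc))) {
          s <- sc[j, ]
          if (nrow(planted) == 0 || !is_planted_site(s)) {
            accidental <- s
            break
          }
        }
        if (!is.null(accidental)) break
      }
      if (is.null(accidental)) break
      # patch one position of the accidental site that is outside every
      # planted interval
      pos <- seq(accidental$start, accidental$end - 1L)
      pos <- pos[!in_planted[pos + 1]]
      if (!length(pos)) {
        stop("accidental site cannot be patched without touching a planted site")
      }
      p <- pos[sample.int(length(pos), 1)]
      b <- substr(seqn, p + 1, p + 1)
      substr(seqn, p + 1, p + 1) <- chartr("ACGT", "CATG", b)
    }
    if (iter == 200) stop("failed to screen background after 200 patches")

    truth <- data.frame(
      mirna_id = planted$mirna_id,
      start = planted$position,
      end = ends,
      site_type = planted$site_type,
      stringsAsFactors = FALSE
    )
    list(sequence = seqn, truth = truth)
  })
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over `Biostrings` used for UTR and miRNA sequence files.
#'
#' @param path FASTA file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path
  )
  invisible(path)
}
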