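# Independent oracles used across the suite. These deliberately re-derive
# results by exhaustive scanning or from-scratch arithmetic, never through
# the code paths they check.

# Exhaustive-offset anchored extraction oracle: for every read, scan every
# possible anchor placement, count mismatches positionally, take the
# fewest-mismatch (ties leftmost) placement, then validate the barcode
# window and the 3' anchor at that single placement.
oracle_extract_all <- function(seqs, cfg) {
  la <- nchar(cfg$anchor5)
  l3 <- nchar(cfg$anchor3)
  bcl <- cfg$bc_length
  a5 <- strsplit(cfg$anchor5, "")[[1]]
  a3 <- if (l3 > 0) strsplit(cfg$anchor3, "")[[1]] else character(0)
  vapply(seqs, function(sq) {
    ch <- strsplit(sq, "")[[1]]
    L <- length(ch)
    if (L < la) return(NA_character_)
    mm <- vapply(seq_len(L - la + 1L), function(off) {
      sum(ch[off:(off + la - 1L)] != a5)
    }, 0)
    best <- min(mm)
    if (best > cfg$max_anchor_mismatch) return(NA_character_)
    off <- which(mm == best)[[1]]
    bc_start <- off + la
    if (bc_start + bcl - 1L > L) return(NA_character_)
    bc <- paste(ch[bc_start:(bc_start + bcl - 1L)], collapse = "")
    if (l3 > 0) {
      a3_start <- bc_start + bcl
      if (a3_start + l3 - 1L > L) return(NA_character_)
      if (sum(ch[a3_start:(a3_start + l3 - 1L)] != a3) >
          cfg$max_anchor_mismatch) return(NA_character_)
    }
    bc
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive-Hamming assignment oracle over the whole map.
oracle_match <- function(obs, map, max_mm) {
  vapply(obs, function(o) {
    oc <- strsplit(o, "")[[1]]
    d <- vapply(map$barcode, function(b) {
      sum(strsplit(b, "")[[1]] != oc)
    }, 0, USE.NAMES = FALSE)
    dmin <- min(d)
    if (dmin > max_mm) return("unassigned")
    if (sum(d == dmin) > 1) return("ambiguous")
    map$promoter_id[[which.min(d)]]
  }, character(1), USE.NAMES = FALSE)
}

# Full demultiplexing oracle: extraction + assignment + tallies.
oracle_count <- function(seqs, map, cfg) {
  bc <- oracle_extract_all(seqs, cfg)
  counts <- structure(integer(nrow(map)), names = map$promoter_id)
  qc <- c(reads_seen = length(seqs), reads_no_anchor = sum(is.na(bc)),
          reads_bc_unassigned = 0L, reads_bc_ambiguous = 0L)
  ok <- bc[!is.na(bc)]
  if (length(ok)) {
    asg <- oracle_match(ok, map, cfg$max_bc_mismatch)
    qc[["reads_bc_unassigned"]] <- sum(asg == "unassigned")
    qc[["reads_bc_ambiguous"]] <- sum(asg == "ambiguous")
    hit <- asg[!(asg %in% c("unassigned", "ambiguous"))]
    for (h in hit) counts[[h]] <- counts[[h]] + 1L
  }
  list(counts = counts, qc = as.list(qc), barcodes = bc)
}

# Exact-substring demultiplexer: first literal occurrence of anchor5,
# exact 3' anchor, exact barcode lookup. Mirrors mismatch limits (0, 0).
exact_substring_count <- function(seqs, map, cfg) {
  counts <- structure(integer(nrow(map)), names = map$promoter_id)
  la <- nchar(cfg$anchor5); l3 <- nchar(cfg$anchor3); bcl <- cfg$bc_length
  for (sq in seqs) {
    off <- regexpr(cfg$anchor5, sq, fixed = TRUE)
    if (off < 0) next
    bc <- substr(sq, off + la, off + la + bcl - 1L)
    if (nchar(bc) < bcl) next
    if (l3 > 0) {
      a3 <- substr(sq, off + la + bcl, off + la + bcl + l3 - 1L)
      if (!identical(a3, cfg$anchor3)) next
    }
    hit <- which(map$barcode == bc)
    if (length(hit) == 1L) counts[[hit]] <- counts[[hit]] + 1L
  }
  counts
}

# Naive agglomerative clustering oracle: recomputes inter-cluster
# distances from the full pairwise matrix at every merge.
naive_linkage_heights <- function(d, method = "complete") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  linkfun <- if (method == "complete") max else min
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        dd <- linkfun(d[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Build a barcode_counts object directly from a named count vector.
make_counts <- function(sample_id, v) {
  structure(list(sample_id = sample_id, counts = v,
                 qc = list(reads_seen = sum(v), reads_no_anchor = 0L,
                           reads_bc_unassigned = 0L,
                           reads_bc_ambiguous = 0L)),
            class = "barcode_counts")
}

# Random reads: template with barcode at a known position plus per-base
# substitution error (independent implementation of the read model).
mutate_reads <- function(reads, error, seed) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  vapply(reads, function(sq) {
    ch <- strsplit(sq, "")[[1]]
    hit <- which(stats::runif(length(ch)) < error)
    for (p in hit) {
      ch[[p]] <- sample(setdiff(alphabet, ch[[p]]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq_plain <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs,
                             "+", qual)), path)
  invisible(path)
}
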