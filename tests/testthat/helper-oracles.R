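# Independent brute-force oracles. These deliberately avoid the package's
# dynamic programs and Biostrings: enumeration and direct scanning only.

.opair <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3L)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2L)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1L)
  0L
}

.ostack <- function(p1, p2) c(-1, -2, -3)[min(p1, p2)]

# all non-crossing pair sets over positions i..j with hairpin loop >= 3
.enum_structures <- function(i, j, pc) {
  if (j - i < 4L) return(list(list()))
  out <- .enum_structures(i, j - 1L, pc)
  for (k in i:(j - 4L)) {
    if (pc[k, j] > 0L) {
      left <- if (k > i) .enum_structures(i, k - 1L, pc) else list(list())
      inner <- .enum_structures(k + 1L, j - 1L, pc)
      for (L in left) for (I in inner) {
        out[[length(out) + 1L]] <- c(L, I, list(c(k, j)))
      }
    }
  }
  out
}

# exhaustive-enumeration MFE under the stacking model
oracle_fold_mfe <- function(seq) {
  s <- chartr("Uu", "TT", toupper(seq))
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  if (n < 5L) return(0)
  pc <- matrix(0L, n, n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) pc[a, b] <- .opair(v[a], v[b])
  best <- 0
  for (st in .enum_structures(1L, n, pc)) {
    if (length(st) == 0L) next
    partner <- rep(NA_integer_, n)
    for (p in st) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
    e <- 0
    for (p in st) {
      a <- p[1]; b <- p[2]
      if (!is.na(partner[a + 1L]) && partner[a + 1L] == b - 1L) {
        e <- e + .ostack(pc[a, b], pc[a + 1L, b - 1L])
      }
    }
    if (e < best) best <- e
  }
  best
}

# exhaustive duplex MFE: antiparallel non-crossing intermolecular pairs
oracle_duplex_mfe <- function(a, b) {
  va <- strsplit(chartr("Uu", "TT", toupper(a)), "")[[1]]
  vb <- strsplit(chartr("Uu", "TT", toupper(b)), "")[[1]]
  la <- length(va); lb <- length(vb)
  best <- 0
  # recursion: pair sets using a-positions >= i, b-positions <= j
  rec <- function(i, j) {
    sets <- list(list())
    if (i > la || j < 1L) return(sets)
    for (ii in i:la) for (jj in seq_len(j)) {
      if (.opair(va[ii], vb[jj]) > 0L) {
        for (S in rec(ii + 1L, jj - 1L)) {
          sets[[length(sets) + 1L]] <- c(list(c(ii, jj)), S)
        }
      }
    }
    sets
  }
  for (st in rec(1L, lb)) {
    if (length(st) < 2L) next
    e <- 0
    for (x in seq_len(length(st) - 1L)) {
      p <- st[[x]]; q <- st[[x + 1L]]
      if (q[1] == p[1] + 1L && q[2] == p[2] - 1L) {
        e <- e + .ostack(.opair(va[p[1]], vb[p[2]]), .opair(va[q[1]], vb[q[2]]))
      }
    }
    if (e < best) best <- e
  }
  best
}

# exhaustive local complementarity alignment (affine gaps, seed double weight)
oracle_align_score <- function(mirna, site, match = 5, wobble = 2,
                               mismatch = -3, gap_open = -9, gap_extend = -4,
                               w_start = 2L, w_end = 8L, w_mult = 2) {
  x <- strsplit(chartr("Uu", "TT", toupper(mirna)), "")[[1]]
  y <- rev(strsplit(chartr("Uu", "TT", toupper(site)), "")[[1]])
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0)
  colscore <- function(i, j) {
    p <- .opair(x[i], y[j])
    s <- if (p >= 2L) match else if (p == 1L) wobble else mismatch
    if (i >= w_start && i <= w_end) s * w_mult else s
  }
  best <- 0
  rec <- function(i, j, sc, last) {
    if (sc > best) best <<- sc
    if (i < n && j < m) rec(i + 1L, j + 1L, sc + colscore(i + 1L, j + 1L), "M")
    if (i < n) rec(i + 1L, j, sc + if (last == "Y") gap_extend else gap_open, "Y")
    if (j < m) rec(i, j + 1L, sc + if (last == "X") gap_extend else gap_open, "X")
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) {
    rec(i0, j0, colscore(i0, j0), "M")
  }
  best
}

# brute-force <=1-mismatch scan of a tag over every genomic position/strand
oracle_map_bruteforce <- function(tag, genome, max_mismatch = 1L) {
  rc_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  L <- nchar(tag)
  traw <- utf8ToInt(tag)
  hits <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[chrom]] else rc_chr(genome[[chrom]])
      clen <- nchar(subject)
      if (clen < L) next
      graw <- utf8ToInt(subject)
      npos <- clen - L + 1L
      mm <- integer(npos)
      for (k in seq_len(L)) {
        mm <- mm + (graw[k:(k + npos - 1L)] != traw[k])
      }
      pos <- which(mm <= max_mismatch)
      if (length(pos) == 0L) next
      gstart <- if (strand == "+") pos else clen - (pos + L - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = gstart, end = gstart + L - 1L, strand = strand,
        mismatches = mm[pos], stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# hypergeometric upper tail by direct summation of exact terms
oracle_hyper_tail <- function(m, M, n, N) {
  if (m <= 0) return(1)
  k <- m:min(n, M)
  sum(exp(lchoose(n, k) + lchoose(N - n, M - k) - lchoose(N, M)))
}

# random DNA string
rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                collapse = "")
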