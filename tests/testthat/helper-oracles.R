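# Independent oracles used across tests. These deliberately avoid the code
# paths they validate.

# realized identity of a mutated pair from the simulator's position list
oracle_identity <- function(genome, mutated) {
  1 - length(mutated$positions) / genome$length_bp
}

# brute-force placement of error-free reads: exact full-length matching on
# both strands via Biostrings PDict (leftmost match; '+' preferred on ties)
oracle_place_exact <- function(sequences, genome) {
  stopifnot(length(unique(nchar(sequences))) == 1)
  subject <- Biostrings::DNAString(genome$sequence)
  find_first <- function(seqs) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
    hits <- Biostrings::matchPDict(pd, subject)
    vapply(as.list(hits), function(h) {
      if (length(h) == 0) NA_integer_ else min(Biostrings::start(h))
    }, integer(1))
  }
  fwd <- find_first(sequences)
  rev <- find_first(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequences))))
  start <- ifelse(!is.na(fwd) & (is.na(rev) | fwd <= rev), fwd, rev)
  strand <- ifelse(!is.na(fwd) & (is.na(rev) | fwd <= rev), "+",
                   ifelse(is.na(rev), NA_character_, "-"))
  data.frame(start = start - 1L, strand = strand, stringsAsFactors = FALSE)
}

# plain quadratic Needleman-Wunsch with match 1 / mismatch 0 /
# gap open -11 / gap extend -1 (affine), identity over columns excluding
# terminal gaps -- the reference for the clustering aligner
oracle_nw_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9; open <- -11; ext <- -1
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- open + (i - 2) * ext
  for (j in 2:(m + 1)) Y[1, j] <- open + (j - 2) * ext
  ptrM <- matrix(0L, n + 1, m + 1); ptrX <- matrix(0L, n + 1, m + 1)
  ptrY <- matrix(0L, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else 0
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s; ptrM[i, j] <- k
      candx <- c(M[i - 1, j] + open, X[i - 1, j] + ext)
      kx <- which.max(candx); X[i, j] <- candx[kx]; ptrX[i, j] <- kx
      candy <- c(M[i, j - 1] + open, Y[i, j - 1] + ext)
      ky <- which.max(candy); Y[i, j] <- candy[ky]; ptrY[i, j] <- ky
    }
  }
  # traceback
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  pa <- character(0); pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      pa <- c(av[i - 1], pa); pb <- c(bv[j - 1], pb)
      state <- ptrM[i, j]; i <- i - 1; j <- j - 1
      if (state == 0) state <- if (i > 1) 2 else 3
    } else if (state == 2) {
      pa <- c(av[i - 1], pa); pb <- c("-", pb)
      ns <- ptrX[i, j]; i <- i - 1
      state <- if (ns == 1) 1 else 2
      if (i == 1 && j > 1) state <- 3
    } else {
      pa <- c("-", pa); pb <- c(bv[j - 1], pb)
      ns <- ptrY[i, j]; j <- j - 1
      state <- if (ns == 1) 1 else 3
      if (j == 1 && i > 1) state <- 2
    }
  }
  gap <- pa == "-" | pb == "-"
  both <- which(!gap)
  if (length(both) == 0) return(0)
  cols <- both[1]:both[length(both)]
  sum(pa[cols] == pb[cols] & pa[cols] != "-") / length(cols)
}

# random amino-acid sequence
random_aa <- function(n, seed) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  picocult:::with_seed(seed, paste(sample(aa, n, replace = TRUE), collapse = ""))
}

# mutate an AA sequence at a given number of positions
mutate_aa <- function(seq, n_mut, seed) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  v <- strsplit(seq, "")[[1]]
  picocult:::with_seed(seed, {
    pos <- sample(seq_along(v), n_mut)
    for (p in pos) v[p] <- sample(setdiff(aa, v[p]), 1)
    paste(v, collapse = "")
  })
}
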