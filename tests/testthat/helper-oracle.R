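# Brute-force indel reclassifier used as an independent oracle.
# Deliberately shares no code with the package: it works on exploded
# character vectors with plain loops, scanning the reference directly.

oracle_indel <- function(seq_string, pos, ref, alt) {
  ch <- strsplit(seq_string, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (nchar(ref) > nchar(alt)) {          # deletion
    del <- strsplit(substr(ref, 2, nchar(ref)), "")[[1]]
    L <- length(del)
    first_after <- pos + 1 + L            # index just past the deleted block
    if (L == 1) {
      run <- 1
      i <- first_after
      while (i <= length(ch) && ch[i] == del[1]) { run <- run + 1; i <- i + 1 }
      b <- if (del[1] %in% c("A", "G")) comp[[del[1]]] else del[1]
      return(sprintf("1:Del:%s:%d", b, min(run, 6)))
    }
    # tandem repeat: count whole copies of the deleted block 3' of it
    copies <- 1
    i <- first_after
    repeat {
      if (i + L - 1 > length(ch)) break
      if (!all(ch[i:(i + L - 1)] == del)) break
      copies <- copies + 1
      i <- i + L
    }
    lbin <- min(L, 5)
    if (copies >= 2) return(sprintf("%d:Del:R:%d", lbin, min(copies, 6)))
    # microhomology: shared prefix with 3' flank / shared suffix with 5' flank
    p <- 0
    while (p < L - 1 && first_after + p <= length(ch) &&
           ch[first_after + p] == del[p + 1]) p <- p + 1
    s <- 0
    while (s < L - 1 && pos - s >= 1 && ch[pos - s] == del[L - s]) s <- s + 1
    mh <- max(p, s)
    if (mh >= 1) {
      cap <- c(1, 2, 3, 5)[lbin - 1]
      return(sprintf("%d:Del:M:%d", lbin, min(mh, cap)))
    }
    return(sprintf("%d:Del:R:1", lbin))
  }
  # insertion
  ins <- strsplit(substr(alt, 2, nchar(alt)), "")[[1]]
  L <- length(ins)
  first_after <- pos + 1
  if (L == 1) {
    run <- 0
    i <- first_after
    while (i <= length(ch) && ch[i] == ins[1]) { run <- run + 1; i <- i + 1 }
    b <- if (ins[1] %in% c("A", "G")) comp[[ins[1]]] else ins[1]
    return(sprintf("1:Ins:%s:%d", b, min(run, 5)))
  }
  copies <- 0
  i <- first_after
  repeat {
    if (i + L - 1 > length(ch)) break
    if (!all(ch[i:(i + L - 1)] == ins)) break
    copies <- copies + 1
    i <- i + L
  }
  sprintf("%d:Ins:R:%d", min(L, 5), min(copies, 5))
}

# direct Bayes evaluation without log-space tricks: the three equations as
# plain products, for tiny K and category spaces
oracle_posterior <- function(counts, templates, priors) {
  lik <- apply(templates, 1, function(p) prod(p ^ counts))
  evidence <- sum(lik * priors)
  lik * priors / evidence
}

# brute-force AUC by pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
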