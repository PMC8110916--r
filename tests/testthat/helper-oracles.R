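# Independent brute-force oracles, deliberately written without reusing
# any implementation path from the package.

# classical moments straight from the definitions
oracleMoments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  if (m2 <= .Machine$double.eps * max(1, m^2))
    return(c(mean = m, var = 0, skew = 0, kurt = 0))
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  c(mean = m, var = m2, skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

# speech-graph statistics by adjacency-list enumeration
oracleGraphStats <- function(tokenLists) {
  tokenLists <- lapply(tokenLists, tolower)
  words <- unique(unlist(tokenLists))
  N <- length(words)
  edges <- list()
  for (u in tokenLists) if (length(u) >= 2)
    for (i in seq_len(length(u) - 1))
      edges[[length(edges) + 1L]] <- c(u[i], u[i + 1])
  E <- length(edges)
  keys <- vapply(edges, paste, "", collapse = "\r")
  tab <- table(keys)
  distinct <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))

  adj <- function(a, b) any(distinct[, 1] == a & distinct[, 2] == b)
  l1 <- if (E) sum(distinct[, 1] == distinct[, 2]) else 0
  l2 <- 0; l3 <- 0
  if (E && N >= 2) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i < j && adj(words[i], words[j]) && adj(words[j], words[i]))
        l2 <- l2 + 1
    }
    if (N >= 3) {
      combos <- utils::combn(N, 3)
      for (c_ in seq_len(ncol(combos))) {
        tri <- words[combos[, c_]]
        perms <- list(tri, tri[c(1, 3, 2)])
        for (p in perms) {
          if (adj(p[1], p[2]) && adj(p[2], p[3]) && adj(p[3], p[1]))
            l3 <- l3 + 1
        }
      }
    }
  }
  nonSelf <- if (E) sum(distinct[, 1] != distinct[, 2]) else 0
  density <- if (N > 1) nonSelf / (N * (N - 1)) else 0

  # BFS shortest paths on the distinct-edge digraph
  nbr <- lapply(words, function(w)
    if (E) distinct[distinct[, 1] == w & distinct[, 2] != w, 2] else
      character(0))
  names(nbr) <- words
  dists <- matrix(Inf, N, N, dimnames = list(words, words))
  for (s in words) {
    dists[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w2 in nbr[[v]]) if (!is.finite(dists[s, w2])) {
        dists[s, w2] <- dists[s, v] + 1
        queue <- c(queue, w2)
      }
    }
  }
  finite <- dists[is.finite(dists) & dists > 0]
  diameter <- if (length(finite)) max(finite) else 0
  aspl <- if (length(finite)) mean(finite) else 0

  # weak components via union of both directions
  comp <- seq_len(N); names(comp) <- words
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (E) for (r in seq_len(nrow(distinct))) {
    a <- find(match(distinct[r, 1], words))
    b <- find(match(distinct[r, 2], words))
    comp[a] <- b
  }
  lcc <- max(table(vapply(seq_len(N), find, 1L)))
  # strong components: mutual reachability
  reach <- is.finite(dists)
  scc <- rep(0L, N)
  cid <- 0L
  for (i in seq_len(N)) if (scc[i] == 0L) {
    cid <- cid + 1L
    scc[reach[i, ] & reach[, i]] <- cid
  }
  lsc <- max(table(scc))

  c(nodes = N, edges = E, repeated_edges = sum(tab > 1), l1 = l1,
    l2 = l2, l3 = l3, lcc = as.numeric(lcc), lsc = as.numeric(lsc),
    density = density, diameter = diameter, aspl = aspl,
    mean_degree = if (N) 2 * E / N else 0)
}

# Kruskal-Wallis H with tie correction, from the textbook formula
oracleKW <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  offs <- cumsum(c(0, lengths(groups)))
  H <- 0
  for (i in seq_along(groups)) {
    ri <- r[(offs[i] + 1):offs[i + 1]]
    H <- H + length(ri) * (mean(ri) - (n + 1) / 2)^2
  }
  H <- 12 / (n * (n + 1)) * H
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / corr
}

# vocabulary richness by direct counting loops
oracleRichness <- function(tokens) {
  tokens <- tolower(tokens)
  N <- length(tokens)
  seen <- c(); counts <- c()
  for (tk in tokens) {
    i <- match(tk, seen)
    if (is.na(i)) { seen <- c(seen, tk); counts <- c(counts, 1) }
    else counts[i] <- counts[i] + 1
  }
  V <- length(seen); V1 <- sum(counts == 1); V2 <- sum(counts == 2)
  hden <- 1 - V1 / V
  if (hden <= 0) hden <- 1e-3
  c(ttr = V / N, brunet = N^(V^-0.165), honore = 100 * log(N) / hden,
    guiraud = V / sqrt(N), sichel = V2 / V)
}

oracleCosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# tiny deterministic test transcripts -----------------------------------
fixtureChatText <- function() {
  paste(
    "@UTF8",
    "@Begin",
    "@Languages:\teng",
    "@ID:\teng|fix01|PAR|67;|male|||Participant|||",
    "*PAR:\tthe boy is taking a cookie .",
    "*INV:\tokay go on .",
    "*PAR:\t&-um the water is (.) overflowing .",
    "*PAR:\tshe is <washing the> [//] drying the dishes .",
    "%mor:\tignored tier",
    "*PAR:\txxx the stool is falling .",
    "@End", sep = "\n")
}

# small cached synthetic cohort shared across tests (cheap audio rate)
tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(cohortConfig(n_per_group = 4, seed = 303,
                                            audio_rate = 8000))
    cache
  }
})

tinyFeatureSet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- extractFeatures(tinyCohort())
    cache
  }
})

# Gaussian feature-matrix cohort with planted mean shifts (for the
# differentiation power analysis); independent of the speech pipeline
gaussianPlantCohort <- function(n_per_group = 54, m = 509, n_planted = 13,
                                shift = 1.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_group * m), 2 * n_per_group, m)
  planted <- seq_len(n_planted)
  X[seq_len(n_per_group), planted] <- X[seq_len(n_per_group), planted] +
    shift
  colnames(X) <- sprintf("f%03d", seq_len(m))
  list(X = X,
       label = rep(c("AD", "non-AD"), each = n_per_group),
       planted = planted)
}
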