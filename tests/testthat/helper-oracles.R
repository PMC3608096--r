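# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: the likelihood oracle enumerates
# founder ordered genotypes and per-meiosis transmission indicators; the
# exact-test oracle enumerates tables via the multivariate hypergeometric
# mass written from factorials.

# haplotype encoding matches the model definition (h = 2*d + m) but the
# computation below is a direct enumeration, not peeling
.oHapFromChoice <- function(g, k) {
  h1 <- g %/% 4L; h2 <- g %% 4L
  d1 <- h1 %/% 2L; m1 <- h1 %% 2L
  d2 <- h2 %/% 2L; m2 <- h2 %% 2L
  out <- integer(length(g))
  out[k == 0L] <- h1[k == 0L]
  out[k == 1L] <- h2[k == 1L]
  out[k == 2L] <- (2L * d1 + m2)[k == 2L]
  out[k == 3L] <- (2L * d2 + m1)[k == 3L]
  out
}

# Full enumeration of the two-locus likelihood: founder ordered genotypes
# (16 states) x per-non-founder transmission indicator pairs, pruned on
# observed marker dosages as individuals are added in topological order.
oracleLogLik <- function(ped, dosage, altFreq, model, theta) {
  df <- pedigreeMembers(ped)
  n <- nrow(df)
  dos <- setNames(rep(NA_integer_, n), df$id)
  dos[names(dosage)] <- as.integer(dosage)
  pen <- model@penetrance
  q <- model@diseaseFreq
  pd <- c(1 - q, q); pm <- c(1 - altFreq, altFreq)
  hprior <- c(pd[1] * pm[1], pd[1] * pm[2], pd[2] * pm[1], pd[2] * pm[2])
  gPrior <- sapply(0:15, function(g) hprior[g %/% 4 + 1] * hprior[g %% 4 + 1])
  w <- c((1 - theta) / 2, (1 - theta) / 2, theta / 2, theta / 2)
  gMarker <- sapply(0:15, function(g)
    (g %/% 4) %% 2 + (g %% 4) %% 2)
  gDisease <- sapply(0:15, function(g)
    (g %/% 4) %/% 2 + (g %% 4) %/% 2)
  # penetrance factor lookup: row = affection, column = genotype 0..15
  penTab <- rbind(affected = pen[gDisease + 1],
                  unaffected = 1 - pen[gDisease + 1],
                  unknown = rep(1, 16))
  penOfVec <- function(aff, g) penTab[aff, g + 1]
  # topological order
  ord <- character()
  done <- setNames(is.na(df$father), df$id)
  ord <- df$id[done]
  while (length(ord) < n) {
    for (id in df$id[!done]) {
      f <- df$father[match(id, df$id)]; m <- df$mother[match(id, df$id)]
      if (done[f] && done[m]) { ord <- c(ord, id); done[id] <- TRUE }
    }
  }
  G <- matrix(integer(0), nrow = 1, ncol = 0)
  P <- 1
  colnamesG <- character()
  for (id in ord) {
    isF <- is.na(df$father[match(id, df$id)])
    if (isF) {
      states <- 0:15
      if (!is.na(dos[id])) states <- states[gMarker[states + 1] == dos[id]]
      pr <- gPrior[states + 1] *
        penOfVec(df$affection[match(id, df$id)], states)
      nc <- nrow(G); ns <- length(states)
      G <- G[rep(seq_len(nc), each = ns), , drop = FALSE]
      G <- cbind(G, rep(states, nc))
      P <- rep(P, each = ns) * rep(pr, nc)
    } else {
      f <- df$father[match(id, df$id)]; m <- df$mother[match(id, df$id)]
      fi <- match(f, colnamesG); mi <- match(m, colnamesG)
      choices <- expand.grid(kf = 0:3, km = 0:3)
      wch <- w[choices$kf + 1] * w[choices$km + 1]
      keepCh <- wch > 0
      choices <- choices[keepCh, ]; wch <- wch[keepCh]
      nc <- nrow(G); ns <- nrow(choices)
      idx <- rep(seq_len(nc), each = ns)
      kf <- rep(choices$kf, nc); km <- rep(choices$km, nc)
      hp <- .oHapFromChoice(G[idx, fi], kf)
      hm <- .oHapFromChoice(G[idx, mi], km)
      g <- 4L * hp + hm
      pr <- rep(wch, nc) * penOfVec(df$affection[match(id, df$id)], g)
      if (!is.na(dos[id])) pr[gMarker[g + 1] != dos[id]] <- 0
      P <- P[idx] * pr
      G <- cbind(G[idx, , drop = FALSE], g)
      keep <- P > 0
      G <- G[keep, , drop = FALSE]; P <- P[keep]
    }
    colnamesG <- c(colnamesG, id)
    if (!nrow(G)) return(-Inf)
  }
  log(sum(P))
}

# Disease-locus-only likelihood (no marker), by direct enumeration over
# per-individual disease genotypes 0/1/2.
oracleDiseaseOnly <- function(ped, model) {
  df <- pedigreeMembers(ped)
  q <- model@diseaseFreq; pen <- model@penetrance
  prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  trans <- function(gp) switch(gp + 1, c(1, 0), c(0.5, 0.5), c(0, 1))
  grid <- do.call(expand.grid, rep(list(0:2), nrow(df)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    p <- 1
    for (i in seq_len(nrow(df))) {
      if (is.na(df$father[i])) {
        p <- p * prior[g[i] + 1]
      } else {
        fi <- match(df$father[i], df$id); mi <- match(df$mother[i], df$id)
        pa <- trans(g[fi]); ma <- trans(g[mi])
        pt <- c(pa[1] * ma[1],
                pa[1] * ma[2] + pa[2] * ma[1],
                pa[2] * ma[2])
        p <- p * pt[g[i] + 1]
      }
      p <- p * switch(df$affection[i], affected = pen[g[i] + 1],
                      unaffected = 1 - pen[g[i] + 1], 1)
      if (p == 0) break
    }
    tot <- tot + p
  }
  log(tot)
}

# Exact 3x2 test by independent enumeration: nested loops over the first
# column, multivariate hypergeometric probability from factorials.
oracleFisher3x2 <- function(tab) {
  N <- sum(tab)
  if (N == 0) return(1)
  r <- rowSums(tab); cs <- colSums(tab)
  lp <- function(a) {
    b <- r - a
    if (any(b < 0)) return(NA_real_)
    sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(c(a, b)))
  }
  pObs <- lp(tab[, 1])
  tot <- 0
  for (a1 in 0:r[1]) for (a2 in 0:r[2]) {
    a3 <- cs[1] - a1 - a2
    if (a3 < 0 || a3 > r[3]) next
    p <- lp(c(a1, a2, a3))
    if (!is.na(p) && p <= pObs + log1p(1e-12)) tot <- tot + exp(p)
  }
  min(1, tot)
}
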