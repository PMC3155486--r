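# Fixture pedigrees (built in code, deterministic) and independent oracles.

trio_pedigree <- function() {
  pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
}

# founders + two full-sib children
sib_pedigree <- function() {
  pedigree(c("A", "B", "C", "D"), c(NA, NA, "A", "A"), c(NA, NA, "B", "B"))
}

# 20 members, 4 generations, with a double-first-cousin union so the last
# generation is inbred (F = 1/8)
fixture_pedigree20 <- function() {
  id <- c(paste0("F", 1:6), paste0("C", 1:7), paste0("D", 1:5), "E1", "E2")
  fa <- c(rep(NA, 6), "F1", "F1", "F1", "F3", "F3", "F5", "F5",
          "C1", "C1", "C2", "C2", "C3", "D1", "D1")
  mo <- c(rep(NA, 6), "F2", "F2", "F2", "F4", "F4", "F6", "F6",
          "C4", "C4", "C5", "C5", "C6", "D3", "D3")
  pedigree(id, fa, mo)
}

# balanced 10v10 sample: one perfectly separating SNP + noise SNPs
separable_data <- function(n_noise = 50, seed = 1, sep_col = 1L) {
  set.seed(seed)
  n <- 20L
  G <- matrix(sample(0:2, n * (n_noise + 1L), replace = TRUE), n,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("v", seq_len(n_noise + 1L))))
  y <- rep(1:0, each = n / 2)
  G[, sep_col] <- ifelse(y == 1L, 2L, 0L)
  list(G = G, y = y, sep = colnames(G)[sep_col])
}

# ---- independent oracles ------------------------------------------------

# maximum total over all injections of rows into columns (brute force)
lap_brute_force <- function(K) {
  I <- nrow(K)
  J <- ncol(K)
  best <- -Inf
  rec <- function(i, used, tot) {
    if (i > I) {
      if (tot > best) best <<- tot
      return(invisible())
    }
    for (j in seq_len(J)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, tot + K[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(J), 0)
  best
}

# two-sided Fisher p by full enumeration over all tables with the observed
# margins (point-probability rule)
fisher_brute_force <- function(tab) {
  r <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  log_prob <- function(row1) {
    sum(lchoose(cs, row1)) - lchoose(n, r[1])
  }
  p_obs <- log_prob(tab[1, ])
  g <- length(cs)
  total <- 0
  if (g == 2) {
    for (a in 0:min(r[1], cs[1])) {
      b <- r[1] - a
      if (b < 0 || b > cs[2]) next
      lp <- log_prob(c(a, b))
      if (lp <= p_obs + 1e-7) total <- total + exp(lp)
    }
  } else {
    for (a in 0:min(r[1], cs[1])) {
      for (b in 0:min(r[1] - a, cs[2])) {
        cc <- r[1] - a - b
        if (cc < 0 || cc > cs[3]) next
        lp <- log_prob(c(a, b, cc))
        if (lp <= p_obs + 1e-7) total <- total + exp(lp)
      }
    }
  }
  min(1, total)
}

# random 2xg table with fixed positive margins and grand total <= max_total
random_table <- function(g = 2, max_total = 30) {
  repeat {
    tab <- matrix(rpois(2 * g, lambda = 3), 2, g)
    if (sum(tab) >= 2 && sum(tab) <= max_total &&
        all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# step-up BH, written as the independent loop from largest to smallest p
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}
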