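# Independent oracles and fixture builders used across the suite.

# tiny genome: 3 placed chromosomes + 1 scaffold, uniform random sequence
toy_genome <- function(len = 1000, seed = 99) {
  set.seed(seed)
  mk <- function() paste(sample(c("A", "C", "G", "T"), len, TRUE),
                         collapse = "")
  ems_genome(c(Chr01 = mk(), Chr02 = mk(), Chr03 = mk(), scaffold_001 = mk()),
             placed = c("Chr01", "Chr02", "Chr03"))
}

toy_roles <- function(n_mut = 9, n_wt = 5) {
  sample_roles(stats::setNames(
    c(rep("mutant", n_mut), rep("wildtype", n_wt)),
    c(paste0("R", 2:(n_mut + 1)), paste0("R", (n_mut + 2):(n_mut + n_wt + 1)))))
}

# random multi-sample site table exercising every cascade rule
random_sites <- function(n, genome, roles, seed) {
  set.seed(seed)
  chroms <- names(genome$seq)
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- vapply(chrom, function(c) sample.int(genome$lengths[[c]], 1), 0L)
  ref <- vapply(seq_len(n), function(i) genome_base(genome, chrom[i], pos[i]), "")
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  states <- c("homref", "het", "homalt", "missing")
  gt <- matrix(NA_character_, n, length(roles),
               dimnames = list(NULL, names(roles)))
  for (j in seq_along(roles)) {
    st <- sample(states, n, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
    gt[, j] <- ifelse(st == "homref", paste(ref, ref, sep = "/"),
               ifelse(st == "het", paste(pmin(ref, alt), pmax(ref, alt), sep = "/"),
               ifelse(st == "homalt", paste(alt, alt, sep = "/"),
                      NA_character_)))
  }
  variant_table(chrom, pos, ref, alt, gt)
}

# naive per-site rule evaluator: re-states the cascade + attribution rules
# site by site, independently of the vectorized implementation
naive_cascade <- function(sites, roles, genome) {
  wt <- names(roles)[roles == "wildtype"]
  mut <- names(roles)[roles == "mutant"]
  kept <- logical(nrow(sites))
  calls <- stats::setNames(vector("list", length(mut)), mut)
  for (m in mut) calls[[m]] <- character(0)
  for (i in seq_len(nrow(sites))) {
    wg <- unlist(sites[i, wt])
    if (anyNA(wg) || length(unique(wg)) != 1) next            # step 1
    cons <- wg[1]
    homref <- paste(sites$ref[i], sites$ref[i], sep = "/")
    if (cons != homref) next                                   # step 2
    mg <- unlist(sites[i, mut])
    if (!anyNA(mg) && length(unique(mg)) == 1 && mg[1] != homref) next # step 3
    if (!sites$chrom[i] %in% genome$placed) next               # step 4
    unique_mut <- FALSE                                        # step 5
    for (j in seq_along(mut)) {
      gj <- mg[j]
      if (is.na(gj)) next
      others <- mg[-j]
      if (!any(!is.na(others) & others == gj)) unique_mut <- TRUE
    }
    if (!unique_mut) next
    kept[i] <- TRUE
    for (m in mut) {                                           # attribution
      g <- unlist(sites[i, m])
      if (!is.na(g) && g != cons)
        calls[[m]] <- c(calls[[m]], paste(sites$chrom[i], sites$pos[i]))
    }
  }
  list(kept = kept, calls = calls)
}

# closed-form OLS via the normal equations, with slope t-test
ols_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / sstot
  se <- sqrt(ssres / (n - 2) / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# exact hypergeometric upper tail by direct combinatorial ratio (small N)
hyper_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# BH by the direct definition: adj_i = min_{j: p_j >= p_i} p_j * m / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i)
    min(1, min((p * m / r)[p >= p[i] | seq_len(m) == i])), numeric(1))
}

# entanglement straight from its definition on two leaf-label orders
entanglement_oracle <- function(labs1, labs2, L) {
  n <- length(labs1)
  r2 <- match(labs1, labs2)
  sum(abs(seq_len(n) - r2)^L) / sum(abs(seq_len(n) - rev(seq_len(n)))^L)
}

call_keys <- function(callsets) {
  lapply(callsets$calls, function(d)
    if (nrow(d)) paste(d$chrom, d$pos) else character(0))
}
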