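# Shared fixtures, all built in code.

# tiny hand-written panel: 4 samples x 3 variants, hard calls
tiny_panel <- function() {
  variants <- data.frame(id = c("rs1", "rs2", "rs3"), chrom = "1",
                         pos = c(100L, 200L, 300L),
                         a1 = c("A", "C", "G"), a2 = c("G", "T", "A"),
                         stringsAsFactors = FALSE)
  d <- matrix(c(0, 1, 2, 1,
                2, 2, 1, 0,
                0, 0, 1, 1), nrow = 4, ncol = 3)
  genotype_panel(paste0("s", 1:4), variants, d)
}

# moderately sized simulated inputs for training-stage tests
small_sim <- function(seed = 42, n1 = 600, n2 = 1500, p = 30, ...) {
  simulate_dataset(sim_config(n1 = n1, n2 = n2, p = p, seed = seed, ...))
}

# a weight set with given (possibly sparse) weights over a simulated panel
manual_weight_set <- function(panel, w_a, w_b, w_co, mode = "residual") {
  weight_set("pair", panel$variants, w_a, w_b, w_co, mode = mode)
}

random_weight_set <- function(panel, seed, sparsity = 0.5) {
  set.seed(seed)
  p <- nrow(panel$variants)
  draw <- function() rnorm(p) * (runif(p) > sparsity)
  w <- replicate(3, draw(), simplify = FALSE)
  # guarantee each column has signal so the design is full rank
  for (i in 1:3) if (all(w[[i]] == 0)) w[[i]][i] <- 1
  manual_weight_set(panel, w[[1]], w[[2]], w[[3]])
}
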