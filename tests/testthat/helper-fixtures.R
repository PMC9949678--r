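# independent isomorphism oracle (igraph BLISS/VF2), used to cross-check the
# package's canonical-form route
iso_oracle <- function(a, b) {
  if (length(a$cells) != length(b$cells)) return(FALSE)
  igraph::isomorphic(fusomekit:::as_igraph_tree(a),
                     fusomekit:::as_igraph_tree(b))
}

path_tree <- function(n) cyst_tree(cbind(seq_len(n - 1), seq_len(n - 1) + 1))

star_tree <- function(n) cyst_tree(cbind(rep(1L, n - 1), seq_len(n - 1) + 1))

# random labelled tree on cells 1..n via a random Pruefer-like attachment
random_tree <- function(n, seed) {
  set.seed(seed)
  if (n == 1) return(cyst_tree(cells = 1L))
  canals <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1), 1L))
  cyst_tree(canals)
}

# a random topology reachable by synchronous divisions from one cell
random_division_product <- function(n_cells, seed) {
  set.seed(seed)
  tr <- cyst_tree(cells = 1L)
  while (length(tr$cells) < n_cells) {
    ch <- lapply(tr$cells, function(c0) {
      opts <- division_choices(tr, c0)
      opts[[sample.int(length(opts), 1)]]
    })
    tr <- divide_all(tr, ch)
  }
  tr
}

# simulation oracle for the growth model: play the divisions forward,
# adding plug v_k at every new canal, mother keeps beta of it
simulate_growth_oracle <- function(v, beta, k) {
  vol <- c(v[["v0"]])
  for (div in seq_len(k)) {
    n <- length(vol)
    plug <- v[[paste0("v", div)]]
    vol <- c(vol + beta * plug, rep((1 - beta) * plug, n))
  }
  vol / sum(vol)
}

# brute-force minimum-cost assignment for small matrices
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}
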