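# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Minimum total parsimony cost by exhaustive enumeration of all node-state
# assignments (leaves restricted to their observed sets, internals free).
brute_force_length <- function(edges, cells, ordered, nstates, n) {
  nn <- max(edges)
  total <- 0
  for (j in seq_len(ncol(cells))) {
    k <- nstates[j]
    sets <- vector("list", nn)
    for (v in seq_len(nn)) {
      sets[[v]] <- if (v <= n) {
        s <- cells[v, j]
        if (s == "?") 0:(k - 1) else as.integer(strsplit(s, "")[[1]])
      } else 0:(k - 1)
    }
    grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE)
    cost <- rep(0, nrow(grid))
    for (r in seq_len(nrow(edges))) {
      a <- grid[[edges[r, 1]]]
      b <- grid[[edges[r, 2]]]
      cost <- cost + if (ordered[j]) abs(a - b) else as.integer(a != b)
    }
    total <- total + min(cost)
  }
  total
}

# Star-tree (g) bound by enumerating every central state.
brute_force_star <- function(cells_col, ordered, k) {
  scored <- cells_col[cells_col != "?"]
  if (!length(scored)) return(0L)
  sets <- lapply(scored, function(s) as.integer(strsplit(s, "")[[1]]))
  min(vapply(0:(k - 1), function(cc)
    sum(vapply(sets, function(st) min(if (ordered) abs(st - cc)
                                      else as.integer(!(cc %in% st))), 0)),
    numeric(1)))
}

# A random unrooted binary topology over n leaves (edge-matrix form).
random_edges <- function(n) {
  edges <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2,
                  byrow = TRUE)
  if (n < 4) return(edges)
  for (k in 4:n) {
    e <- sample.int(nrow(edges), 1)
    u <- edges[e, 1]; v <- edges[e, 2]
    w <- as.integer(n + k - 2)
    edges[e, ] <- c(u, w)
    edges <- rbind(edges, c(w, v), c(w, k))
  }
  edges
}

# Winding-number point-in-polygon (no tolerance handling): TRUE if the
# point is strictly inside or on the boundary of the convex polygon.
pip_winding <- function(px, py, vx, vy) {
  n <- length(vx)
  sgn <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    sgn[i] <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
  }
  all(sgn >= -1e-12) || all(sgn <= 1e-12)
}

# Bipartition (clade, rooted on first tip) frequencies by direct counting.
clade_frequencies <- function(trees) {
  key_of <- function(phy) {
    n <- length(phy$tip.label)
    keys <- character(0)
    for (node in (n + 1):(n + phy$Nnode)) {
      tips <- character(0)
      stack <- node
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        kids <- phy$edge[phy$edge[, 1] == v, 2]
        for (k in kids) {
          if (k <= n) tips <- c(tips, phy$tip.label[k])
          else stack <- c(stack, k)
        }
      }
      keys <- c(keys, paste(sort(tips), collapse = "|"))
    }
    keys
  }
  tab <- table(unlist(lapply(trees, key_of)))
  tab / length(trees)
}

# The packaged reference summaries in test-friendly form.
table5_baselines <- function() {
  t5 <- fixtures("table5")
  n <- attr(t5, "n")
  rbind(
    data.frame(group = "ungular", variable = t5$variable,
               mean = t5$ungular_mean, variance = t5$ungular_var,
               n = n[["ungular"]], stringsAsFactors = FALSE),
    data.frame(group = "grooming", variable = t5$variable,
               mean = t5$grooming_mean, variance = t5$grooming_var,
               n = n[["grooming"]], stringsAsFactors = FALSE))
}

# Four-group synthetic phalanx specs at the published parameter values;
# falcular and tegular summaries are not published, so those groups use
# plausible claw-like and tegula-like values held fixed across the suite.
four_group_specs <- function(n = c(ungular = 21, grooming = 10,
                                   tegular = 4, falcular = 7)) {
  falc_means <- c(BH_GM = 1.40, BW_GM = 0.95, TPL_GM = 3.60,
                  SH14_GM = 1.00, SW14_GM = 0.55, SW34_GM = 0.35,
                  VFL_TPL = 0.30, SH14_SH34 = 2.60, FSA = 55)
  falc_vars <- c(BH_GM = 0.05, BW_GM = 0.02, TPL_GM = 0.15,
                 SH14_GM = 0.03, SW14_GM = 0.01, SW34_GM = 0.01,
                 VFL_TPL = 0.004, SH14_SH34 = 0.30, FSA = 30)
  teg_means <- c(BH_GM = 1.30, BW_GM = 1.05, TPL_GM = 3.40,
                 SH14_GM = 0.95, SW14_GM = 0.60, SW34_GM = 0.45,
                 VFL_TPL = 0.35, SH14_SH34 = 2.30, FSA = 60)
  teg_vars <- falc_vars
  list(phalanx_group_spec("ungular", n[["ungular"]]),
       phalanx_group_spec("grooming", n[["grooming"]]),
       phalanx_group_spec("tegular", n[["tegular"]], means = teg_means,
                          vars = teg_vars),
       phalanx_group_spec("falcular", n[["falcular"]], means = falc_means,
                          vars = falc_vars))
}
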