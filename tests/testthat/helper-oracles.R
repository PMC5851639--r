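# Independent oracles and hand fixtures used across test files.  These
# deliberately re-derive results with different algorithms than the
# package (matrix flood fill, path enumeration, closed forms).

# Connectivity oracle: repeated neighbour dilation on the open mask
# until a fixed point; connected iff some reached open node touches the
# exterior.  (The package uses a stack-based BFS in C++.)
oracle_connected <- function(grid) {
  occ <- grid$occupancy
  side <- nrow(occ)
  open <- occ == 0L
  reach <- matrix(FALSE, side, side)
  mid <- (side + 1L) %/% 2L
  reach[mid, mid] <- TRUE
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-side, ]
    grown[-side, ] <- grown[-side, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -side]
    grown[, -side] <- grown[, -side] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  # touches exterior: some reached cell has a neighbour coded -1 or is
  # on the matrix edge (outside the stored square entirely)
  pad <- matrix(-1L, side + 2, side + 2)
  pad[2:(side + 1), 2:(side + 1)] <- occ
  for (r in seq_len(side)) {
    for (cc in seq_len(side)) {
      if (!reach[r, cc]) next
      nb <- c(pad[r, cc + 1], pad[r + 2, cc + 1], pad[r + 1, cc],
              pad[r + 1, cc + 2])
      if (any(nb == -1L)) return(TRUE)
    }
  }
  FALSE
}

# Exact FPT pmf by brute-force enumeration of all direction sequences up
# to max_depth (probability (1/4)^depth each).
oracle_enum_pmf <- function(grid, max_depth) {
  occ <- grid$occupancy
  R <- grid$radius
  pmf <- numeric(max_depth)
  recurse <- function(x, y, depth, prob) {
    if (depth >= max_depth) return()
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nx <- x + d[[1]]
      ny <- y + d[[2]]
      if (nx * nx + ny * ny >= R * R) {
        pmf[depth + 1] <<- pmf[depth + 1] + prob / 4
      } else if (occ[ny + R + 1, nx + R + 1] == 1L) {
        recurse(x, y, depth + 1, prob / 4)
      } else {
        recurse(nx, ny, depth + 1, prob / 4)
      }
    }
  }
  recurse(0L, 0L, 0L, 1)
  pmf
}

# A radius-4 grid with a closed ring of obstacles at Chebyshev distance
# 2 sealing the origin in.
ring_grid <- function() {
  side <- 9L
  occ <- matrix(0L, side, side)
  for (x in -2:2) {
    for (y in -2:2) {
      if (max(abs(x), abs(y)) == 2) occ[y + 5, x + 5] <- 1L
    }
  }
  grid_from_mask(occ)
}

# Radius-3 corridor: only (0,0), (1,0), (2,0) open; exit right from
# (2,0).  Its absorption chain has 3 transient states.
corridor_grid <- function() {
  occ <- matrix(1L, 7L, 7L)
  occ[4, 4:6] <- 0L   # y = 0, x = 0, 1, 2
  grid_from_mask(occ)
}

# Total variation distance between an empirical step sample and a pmf.
tv_sample_pmf <- function(steps, pmf) {
  kmax <- max(max(steps), length(pmf))
  emp <- tabulate(steps, nbins = kmax) / length(steps)
  the <- c(pmf, numeric(kmax - length(pmf)))
  sum(abs(emp - the)) / 2
}

make_hist <- function(p, width = 1) {
  rt_histogram(seq(0, by = width, length.out = length(p) + 1), p / sum(p))
}

# Small synthetic move-record table with given per-player RT generators.
toy_records <- function(ratings, params_list, n_moves, seed = 1) {
  rows <- lapply(seq_along(ratings), function(i) {
    rt <- gen_rt_sample(params_list[[i]], n_moves, seed + i)
    data.frame(player_id = sprintf("T%02d", i), rating = ratings[[i]],
               game_id = sprintf("T%02d-G%03d", i, seq_len(n_moves)),
               total_time_s = 300,
               remaining_time_s = 150, rt_s = pmin(rt, 149))
  })
  do.call(rbind, rows)
}
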