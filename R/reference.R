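## Plain-R reference implementation of the simulation engines. Mirrors the
## compiled core rule-for-rule but draws from R's RNG; the test suite checks
## that the two implementations agree in distribution. Slow -- intended for
## validation and small illustrative runs, not for sweeps.

.DX <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.DY <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.NONE <- 9L

.ref_bern <- function(p) {
  if (p <= 0) return(FALSE)
  if (p >= 1) return(TRUE)
  stats::runif(1) < p
}
.ref_cat9 <- function(p) sample.int(9L, 1L, prob = p)

## longest x-monotone sequential path, independent R implementation
.mono_path_r <- function(x, y) {
  n <- length(x)
  seqp <- function(i, j) abs(x[i] - x[j]) <= 4 && abs(y[i] - y[j]) <= 1
  best <- 0L
  best_members <- integer(0)
  for (tie in c(1L, -1L)) {
    ord <- order(-x, tie * y)
    dp <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (seqp(ord[j], ord[i]) && dp[j] + 1L > dp[i]) {
          dp[i] <- dp[j] + 1L
          prev[i] <- j
        }
      }
    }
    bi <- which.max(dp)
    if (dp[bi] > best) {
      best <- dp[bi]
      mem <- integer(0)
      i <- bi
      while (!is.na(i)) {
        mem <- c(mem, ord[i])
        i <- prev[i]
      }
      best_members <- mem
    }
  }
  if (best < n) {
    # exact exhaustive search when the sorted-order DP might not be tight
    # (equal-x groups traversed in opposite y directions)
    seq_mat <- outer(x, x, function(a, b) abs(a - b) <= 4) &
      outer(y, y, function(a, b) abs(a - b) <= 1)
    path_best <- best
    path_members <- best_members
    rec <- function(last, used, path) {
      if (length(path) > path_best) {
        path_best <<- length(path)
        path_members <<- path
      }
      for (j in seq_len(n)) {
        if (!used[j] && seq_mat[last, j] && x[j] <= x[last]) {
          used[j] <- TRUE
          rec(j, used, c(path, j))
          used[j] <- FALSE
        }
      }
    }
    for (i in seq_len(n)) {
      used <- rep(FALSE, n)
      used[i] <- TRUE
      rec(i, used, i)
    }
    best <- path_best
    best_members <- path_members
  }
  list(length = best, members = best_members)
}

.run_simulation_reference <- function(params, seed, max_steps, cumulative,
                                      nL, nF, W, H, return_state,
                                      record_states = FALSE) {
  set.seed(seed)
  model <- .model_code(params)
  ep <- .engine_params(params)
  N <- nL + nF
  row <- H %/% 2L

  st <- matrix(SITE_CLOSED, W, H)   # 1-based [x+1, y+1]
  occ <- matrix(0L, W, H)
  x <- seq_len(N)
  y <- rep(row, N)
  leader <- c(rep(FALSE, nF), rep(TRUE, nL))
  for (a in seq_len(N)) {
    st[x[a] + 1L, y[a] + 1L] <- SITE_OCCUPIED
    occ[x[a] + 1L, y[a] + 1L] <- a
  }
  if (isTRUE(ep$track) && N + 1L < W) st[(N + 2L):W, row + 1L] <- SITE_OPEN

  pol <- rep(.NONE, N)
  dclk <- pclk <- rep(0L, N)
  ext <- rep(FALSE, N)
  plen <- matrix(0L, N, 8)

  extend <- function(a) {
    ext[a] <<- TRUE
    plen[a, ] <<- 0L
    if (leader[a]) {
      plen[a, ] <<- 3L
    } else if (pol[a] != .NONE) {
      plen[a, pol[a]] <<- 3L  # single front-directed ray
    }
  }
  retract <- function(a) {
    ext[a] <<- FALSE
    plen[a, ] <<- 0L
  }
  repolarize <- function(a, d) {
    pol[a] <<- d
    if (ext[a]) extend(a)
  }

  if (model != 0L) {
    shared_dclk <- ep$mdi  # synchronized clocks start at the full interval
    for (a in seq_len(N)) {
      if (!leader[a]) {
        if (isTRUE(ep$sid)) {
          pol[a] <- 1L  # distal
          dclk[a] <- shared_dclk
        } else {
          pol[a] <- .ref_cat9(ep$fdd)
          dclk[a] <- sample.int(ep$mdi + 1L, 1L) - 1L
        }
      }
    }
    shared_pclk <- ep$mpi
    for (a in seq_len(N)) {
      pclk[a] <- if (isTRUE(ep$sip)) shared_pclk else sample.int(ep$mpi + 1L, 1L) - 1L
      extend(a)
    }
  }

  inb <- function(px, py) px >= 0 && px < W && py >= 0 && py < H
  ray_covers <- function(a, d, tx, ty) {
    if (!ext[a] || plen[a, d] == 0L) return(FALSE)
    for (k in seq_len(plen[a, d])) {
      cx <- x[a] + k * .DX[d]
      cy <- y[a] + k * .DY[d]
      if (!inb(cx, cy)) break
      if (cx == tx && cy == ty) return(TRUE)
    }
    FALSE
  }
  covers <- function(a, tx, ty) any(vapply(1:8, ray_covers, logical(1), a = a, tx = tx, ty = ty))
  contacts_of <- function(a) {
    out <- integer(0)
    for (b in seq_len(N)) {
      if (b == a) next
      if (covers(a, x[b], y[b]) || covers(b, x[a], y[a])) out <- c(out, b)
    }
    out
  }
  octdir <- function(dx, dy) {
    ang <- atan2(dy, dx)
    diffs <- abs(atan2(sin(ang - atan2(.DY, .DX)), cos(ang - atan2(.DY, .DX))))
    cand <- which(diffs <= min(diffs) + 1e-12)
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }
  links_of <- function(a) {
    out <- list()
    for (b in seq_len(N)) {
      if (b == a) next
      for (d in 1:8) {
        if (ray_covers(a, d, x[b], y[b])) out[[length(out) + 1L]] <- c(a, d, b)
        if (ray_covers(b, d, x[a], y[a])) out[[length(out) + 1L]] <- c(b, d, a)
      }
    }
    out
  }
  maintain_links <- function(links) {
    for (L in links) {
      o <- L[1]; d <- L[2]; p <- L[3]
      dx <- x[p] - x[o]; dy <- y[p] - y[o]
      len <- plen[o, d]
      along <- FALSE; k <- 0L
      if (.DX[d] == 0L) {
        if (dx == 0L && dy * .DY[d] > 0L) { k <- dy * .DY[d]; along <- TRUE }
      } else if (.DY[d] == 0L) {
        if (dy == 0L && dx * .DX[d] > 0L) { k <- dx * .DX[d]; along <- TRUE }
      } else if (dx * .DY[d] == dy * .DX[d] && dx * .DX[d] > 0L) {
        k <- dx * .DX[d]; along <- TRUE
      }
      if (along && k == len) next
      if (!.ref_bern(if (leader[o]) ep$lmp else ep$fmp)) next
      if (along && k >= 1L && k <= 3L && ext[o]) plen[o, d] <<- k
    }
  }
  tick <- function() {
    for (a in seq_len(N)) {
      if (!leader[a]) {
        if (dclk[a] > 0L) dclk[a] <<- dclk[a] - 1L
        if (dclk[a] == 0L) {
          repolarize(a, .ref_cat9(ep$fdd))
          dclk[a] <<- sample.int(ep$mdi + 1L, 1L) - 1L
        }
      }
      if (pclk[a] > 0L) pclk[a] <<- pclk[a] - 1L
      if (pclk[a] == 0L) {
        if (ext[a]) {
          mediates <- any(vapply(seq_len(N)[-a], function(b) covers(a, x[b], y[b]), logical(1)))
          if (!(mediates && .ref_bern(ep$ppc))) retract(a)
        } else {
          extend(a)
        }
        pclk[a] <<- sample.int(ep$mpi + 1L, 1L) - 1L
      }
    }
  }
  do_move <- function(a, nx, ny) {
    st[x[a] + 1L, y[a] + 1L] <<- SITE_OPEN
    occ[x[a] + 1L, y[a] + 1L] <<- 0L
    x[a] <<- nx
    y[a] <<- ny
    st[nx + 1L, ny + 1L] <<- SITE_OCCUPIED
    occ[nx + 1L, ny + 1L] <<- a
  }
  update_agent <- function(a) {
    d <- .NONE
    contact_induced <- FALSE
    if (model == 0L) {
      d <- .ref_cat9(if (leader[a]) ep$ldd else ep$fdd)
    } else {
      cts <- contacts_of(a)
      if (length(cts) && .ref_bern(if (leader[a]) ep$lmc else ep$fmc)) {
        dirs <- unique(vapply(cts, function(b) octdir(x[b] - x[a], y[b] - y[a]), integer(1)))
        d <- if (length(dirs) == 1L) dirs else dirs[sample.int(length(dirs), 1L)]
        contact_induced <- TRUE  # responding to contact is this step's action
      } else {
        d <- if (leader[a]) .ref_cat9(ep$ldd) else pol[a]
      }
    }
    if (d == .NONE) return(invisible(FALSE))
    nx <- x[a] + .DX[d]; ny <- y[a] + .DY[d]
    if (!inb(nx, ny) || st[nx + 1L, ny + 1L] == SITE_OCCUPIED) {
      # filopodia may retract after an attempt to move towards a contact
      if (contact_induced && .ref_bern(if (leader[a]) ep$lrp else ep$frp)) retract(a)
      return(invisible(FALSE))
    }
    links <- if (model != 0L) links_of(a) else list()
    if (model == 1L) {
      do_move(a, nx, ny)
    } else {
      first_open <- st[nx + 1L, ny + 1L] == SITE_OPEN
      if (!first_open && .ref_bern(ep$pos)) return(invisible(FALSE))
      do_move(a, nx, ny)
      if (first_open) {
        nx2 <- nx + .DX[d]; ny2 <- ny + .DY[d]
        if (inb(nx2, ny2) && st[nx2 + 1L, ny2 + 1L] == SITE_OPEN && .ref_bern(ep$ats)) {
          do_move(a, nx2, ny2)
        }
      }
    }
    if (model != 0L) {
      maintain_links(links)
      if (contact_induced) {
        if (!leader[a]) repolarize(a, d)
        if (.ref_bern(if (leader[a]) ep$lrp else ep$frp)) retract(a)
      }
    }
    invisible(TRUE)
  }

  ch <- .mono_path_r(x, y)
  cx_hist <- numeric(max_steps + 1L)
  cx_hist[1L] <- mean(x[ch$members])
  persistence <- 0L
  reason <- "max_steps"
  history <- if (record_states) list(list(states = st, x = x, y = y)) else NULL
  t <- 0L
  while (t < max_steps) {
    t <- t + 1L
    if (model != 0L) tick()
    for (k in seq_len(N)) update_agent(sample.int(N, 1L))
    if (record_states) {
      history[[t + 1L]] <- list(states = st, x = x, y = y)
    }
    ch <- .mono_path_r(x, y)
    is_chain <- ch$length >= 6L
    cx_hist[t + 1L] <- mean(x[ch$members])
    vel_ok <- (t %% 10L != 0L) || (cx_hist[t + 1L] - cx_hist[t - 9L] >= 1)
    if (!(is_chain && vel_ok) && !cumulative) {
      reason <- "chain_broken"
      break
    }
    if (is_chain && vel_ok) persistence <- persistence + 1L
    if (any(x == W - 1L)) {
      reason <- "target_reached"
      break
    }
  }

  rec <- list(
    persistence = persistence,
    termination_reason = reason,
    final_centroid_x = cx_hist[t + 1L],
    steps = t,
    seed = seed,
    model = class(params)[1]
  )
  if (record_states) rec$history <- history
  if (return_state) {
    grid <- new_grid(W, H)
    grid$states <- st
    rec$state <- list(
      grid = grid,
      agents = data.frame(
        id = seq_len(N),
        role = ifelse(leader, "leader", "follower"),
        x = x, y = y,
        polarized = .direction_names[pol],
        extended = ext
      ),
      protrusion_len = plen
    )
  }
  rec
}
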