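# Brute-force reference implementations used to validate the fast kernels,
# plus small fixture builders. All oracles are deliberately naive.

rand_mask <- function(dims, p = 0.2, seed = 1) {
  set.seed(seed)
  array(stats::runif(prod(dims)) < p, dims)
}

# exhaustive min-over-mask Chebyshev distance
oracle_chessboard <- function(mask) {
  d <- dim(mask)
  out <- array(NA_integer_, d)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  ai <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(prod(d)))
    out[v] <- min(pmax(abs(idx[, 1] - ai[v, 1]),
                       pmax(abs(idx[, 2] - ai[v, 2]),
                            abs(idx[, 3] - ai[v, 3]))))
  out
}

# exhaustive min-over-mask Euclidean distance in mm
oracle_euclid <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  out <- array(NA_real_, d)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  ai <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(prod(d)))
    out[v] <- sqrt(min(((idx[, 1] - ai[v, 1]) * spacing[1])^2 +
                       ((idx[, 2] - ai[v, 2]) * spacing[2])^2 +
                       ((idx[, 3] - ai[v, 3]) * spacing[3])^2))
  out
}

# flood-fill connected components in voxel scan order
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, , drop = FALSE]
  if (connectivity == 6) neigh <- neigh[rowSums(abs(neigh)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  ncomp <- 0L
  for (v in seq_len(prod(d))) {
    if (!mask[v] || lab[v]) next
    ncomp <- ncomp + 1L
    queue <- v
    lab[v] <- ncomp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (s in seq_len(nrow(neigh))) {
        p <- ci + neigh[s, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask[w] && !lab[w]) {
          lab[w] <- ncomp
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

shift_mask <- function(m, o) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(ax) {
    r <- seq_len(d[ax]) - o[ax]
    r
  })
  ok <- lapply(1:3, function(ax) src[[ax]] >= 1 & src[[ax]] <= d[ax])
  ii <- which(ok[[1]]); jj <- which(ok[[2]]); kk <- which(ok[[3]])
  if (!length(ii) || !length(jj) || !length(kk)) return(out)
  out[ii, jj, kk] <- m[src[[1]][ii], src[[2]][jj], src[[3]][kk]]
  out
}

oracle_dilate <- function(m, off) {
  Reduce(`|`, lapply(seq_len(nrow(off)), function(s) shift_mask(m, off[s, ])))
}

oracle_erode <- function(m, off) {
  Reduce(`&`, lapply(seq_len(nrow(off)), function(s) shift_mask(m, -off[s, ])))
}

# per-component fraction of 6-connected exterior face-neighbours in `target`
oracle_perimeter_fractions <- function(lab, ncomp, target) {
  d <- dim(lab)
  out <- numeric(ncomp)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (cc in seq_len(ncomp)) {
    vox <- integer(0)
    for (v in which(lab == cc)) {
      ci <- arrayInd(v, d)
      for (s in seq_len(nrow(shifts))) {
        p <- ci + shifts[s, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (lab[w] != cc) vox <- c(vox, w)
      }
    }
    vox <- unique(vox)
    out[cc] <- if (length(vox)) mean(target[vox]) else 0
  }
  out
}

# per-voxel majority label with ties to the lowest code
oracle_majority <- function(lab_list) {
  n <- length(lab_list[[1]])
  out <- integer(n)
  for (v in seq_len(n)) {
    vals <- vapply(lab_list, function(l) l[v], integer(1))
    tb <- table(vals)
    best <- max(tb)
    out[v] <- min(as.integer(names(tb)[tb == best]))
  }
  out
}

# naive patch-based weighted-voting fusion (mirrors the documented rules)
oracle_fuse <- function(target, atlas_int, atlas_lab, patch_off, search_off,
                        beta) {
  d <- dim(target)
  n <- prod(d)
  out <- integer(n)
  getp <- function(arr, ci, off) {
    vals <- rep(NA_real_, nrow(off))
    for (p in seq_len(nrow(off))) {
      q <- ci + off[p, ]
      if (any(q < 1) || any(q > d)) next
      vals[p] <- arr[q[1], q[2], q[3]]
    }
    vals
  }
  for (v in seq_len(n)) {
    ci <- arrayInd(v, d)
    tp <- getp(target, ci, patch_off)
    labs <- integer(0); ws <- numeric(0)
    for (a in seq_along(atlas_int)) {
      best_r <- -2; best_l <- NA_integer_
      for (s in seq_len(nrow(search_off))) {
        si <- ci + search_off[s, ]
        if (any(si < 1) || any(si > d)) next
        ap <- getp(atlas_int[[a]], si, patch_off)
        keep <- !is.na(tp) & !is.na(ap)
        r <- 0
        if (sum(keep) >= 2 && stats::sd(tp[keep]) > 1e-6 &&
            stats::sd(ap[keep]) > 1e-6)
          r <- stats::cor(tp[keep], ap[keep])
        if (r > best_r) {
          best_r <- r
          best_l <- atlas_lab[[a]][si[1], si[2], si[3]]
        }
      }
      w <- if (best_r > 0) best_r^beta else 0
      if (w > 0) { labs <- c(labs, best_l); ws <- c(ws, w) }
    }
    if (!length(labs)) {
      vals <- vapply(atlas_lab, function(l) l[v], integer(1))
      tb <- table(vals)
      out[v] <- min(as.integer(names(tb)[tb == max(tb)]))
    } else {
      sums <- tapply(ws, labs, sum)
      best <- max(sums)
      out[v] <- min(as.integer(names(sums)[sums >= best - 1e-12]))
    }
  }
  array(out, d)
}

# exhaustive convex-hull voxelisation: every point triple whose plane
# supports the cloud contributes a half-space constraint; a voxel centre is
# inside iff it satisfies all of them
oracle_hull_mask <- function(mask) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE) - 1
  n <- nrow(pts)
  eps <- 1e-7
  planes <- list()
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    u <- pts[b, ] - pts[a, ]
    v <- pts[cc, ] - pts[a, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (sum(nrm^2) < 1e-12) next
    side <- as.matrix(sweep(pts, 2, pts[a, ])) %*% nrm
    if (all(side <= eps)) planes[[length(planes) + 1]] <- c(nrm, sum(nrm * pts[a, ]))
    else if (all(side >= -eps)) planes[[length(planes) + 1]] <- c(-nrm, -sum(nrm * pts[a, ]))
  }
  vox <- arrayInd(seq_len(prod(d)), d) - 1
  inside <- rep(TRUE, prod(d))
  for (pl in planes) {
    nn <- sqrt(sum(pl[1:3]^2))
    inside <- inside & (vox %*% pl[1:3] - pl[4]) / nn <= eps
  }
  array(inside, d)
}

# cached phantoms (several test files share them)
.ph_cache <- new.env()
get_phantom <- function(seed = 1, n = 64) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.ph_cache[[key]]))
    .ph_cache[[key]] <- make_phantom(phantom_spec(n = n, seed = seed))
  .ph_cache[[key]]
}

label_dice <- function(a, b, codes) {
  dice(array(a %in% codes, dim(a)), array(b %in% codes, dim(b)))
}

gm_family <- function(sch) c(sch$cortical_gm_lh, sch$cortical_gm_rh)
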