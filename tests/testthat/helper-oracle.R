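# Independent brute-force oracles. Everything here is computed with explicit
# loops straight from the definitions, deliberately avoiding the vectorized
# code paths of the package.

# --- GLCM: loop over all pixel pairs ----------------------------------------
oracle_glcm <- function(q, ng, off) {
  n <- nrow(q); p <- ncol(q)
  m <- matrix(0, ng, ng)
  for (r in 1:n) for (c in 1:p) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= p) {
      m[q[r, c], q[r2, c2]] <- m[q[r, c], q[r2, c2]] + 1
      m[q[r2, c2], q[r, c]] <- m[q[r2, c2], q[r, c]] + 1
    }
  }
  m / sum(m)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) for (j in 1:ng) { mu_x <- mu_x + i * P[i, j]; mu_y <- mu_y + j * P[i, j] }
  sx2 <- 0; sy2 <- 0; sxy <- 0
  energy <- 0; contrast <- 0; varr <- 0; homog <- 0; sumavg <- 0
  ent <- 0; diss <- 0; acorr <- 0; shade <- 0; prom <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- P[i, j]
    sx2 <- sx2 + (i - mu_x)^2 * pij; sy2 <- sy2 + (j - mu_y)^2 * pij
    sxy <- sxy + (i - mu_x) * (j - mu_y) * pij
    energy <- energy + pij^2
    contrast <- contrast + (i - j)^2 * pij
    varr <- varr + (i - mu_x)^2 * pij
    homog <- homog + pij / (1 + abs(i - j))
    sumavg <- sumavg + (i + j) * pij
    if (pij > 0) ent <- ent - pij * log2(pij)
    diss <- diss + abs(i - j) * pij
    acorr <- acorr + i * j * pij
    shade <- shade + (i + j - mu_x - mu_y)^3 * pij
    prom <- prom + (i + j - mu_x - mu_y)^4 * pij
  }
  corr <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  c(glcm_energy = energy, glcm_contrast = contrast, glcm_correlation = corr,
    glcm_variance = varr, glcm_homogeneity = homog, glcm_sum_average = sumavg,
    glcm_entropy = ent, glcm_dissimilarity = diss, glcm_autocorr = acorr,
    glcm_cluster_shade = shade, glcm_cluster_prom = prom)
}

# --- GLRLM: walk every line pixel by pixel ----------------------------------
oracle_glrlm <- function(q, ng, off) {
  n <- nrow(q); p <- ncol(q)
  m <- matrix(0, ng, max(n, p))
  dy <- off[1]; dx <- off[2]
  for (r0 in 1:n) for (c0 in 1:p) {
    # line start: stepping backwards leaves the image
    if (r0 - dy >= 1 && r0 - dy <= n && c0 - dx >= 1 && c0 - dx <= p) next
    r <- r0; c <- c0
    val <- q[r, c]; len <- 0
    while (r >= 1 && r <= n && c >= 1 && c <= p) {
      if (q[r, c] == val) {
        len <- len + 1
      } else {
        m[val, len] <- m[val, len] + 1
        val <- q[r, c]; len <- 1
      }
      r <- r + dy; c <- c + dx
    }
    m[val, len] <- m[val, len] + 1
  }
  m
}

# shared run/zone statistics, looped
oracle_rl_features <- function(m, n_pixels, names_out) {
  ns <- sum(m); ng <- nrow(m); sl <- ncol(m)
  f <- numeric(13)
  mu_i <- 0; mu_l <- 0
  for (i in 1:ng) for (l in 1:sl) {
    mu_i <- mu_i + i * m[i, l] / ns; mu_l <- mu_l + l * m[i, l] / ns
  }
  for (i in 1:ng) for (l in 1:sl) {
    x <- m[i, l]
    f[1] <- f[1] + x / l^2
    f[2] <- f[2] + x * l^2
    f[6] <- f[6] + x / i^2
    f[7] <- f[7] + x * i^2
    f[8] <- f[8] + x / (i^2 * l^2)
    f[9] <- f[9] + x * i^2 / l^2
    f[10] <- f[10] + x * l^2 / i^2
    f[11] <- f[11] + x * i^2 * l^2
    f[12] <- f[12] + (i - mu_i)^2 * x / ns
    f[13] <- f[13] + (l - mu_l)^2 * x / ns
  }
  for (i in 1:ng) f[3] <- f[3] + sum(m[i, ])^2
  for (l in 1:sl) f[4] <- f[4] + sum(m[, l])^2
  f[c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11)] <-
    f[c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11)] / ns
  f[5] <- ns / n_pixels
  stats::setNames(f, names_out)
}

# --- GLSZM: recursive flood fill --------------------------------------------
oracle_zones <- function(q) {
  n <- nrow(q); p <- ncol(q)
  seen <- matrix(FALSE, n, p)
  zones <- list()
  for (r in 1:n) for (c in 1:p) {
    if (seen[r, c]) next
    lvl <- q[r, c]
    stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= p &&
            !seen[rr, cc] && q[rr, cc] == lvl) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lvl, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(q, ng) {
  zs <- oracle_zones(q)
  m <- matrix(0, ng, max(zs[, "size"]))
  for (i in seq_len(nrow(zs))) {
    m[zs[i, "level"], zs[i, "size"]] <- m[zs[i, "level"], zs[i, "size"]] + 1
  }
  m
}

# --- NGTDM: per-pixel neighbor means ----------------------------------------
oracle_ngtdm_features <- function(q, ng) {
  n <- nrow(q); p <- ncol(q)
  s <- numeric(ng); cnt <- numeric(ng)
  for (r in 1:n) for (c in 1:p) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= n && cc >= 1 && cc <= p) nb <- c(nb, q[rr, cc])
    }
    i <- q[r, c]
    s[i] <- s[i] + abs(i - mean(nb))
    cnt[i] <- cnt[i] + 1
  }
  ntot <- sum(cnt); pr <- cnt / ntot
  nz <- which(pr > 0); ngp <- length(nz); eps <- 1e-12
  coarse <- 1 / (eps + sum(pr * s))
  contrast <- 0
  if (ngp > 1) {
    for (i in nz) for (j in nz) contrast <- contrast + pr[i] * pr[j] * (i - j)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / ntot
  }
  den <- 0
  for (i in nz) for (j in nz) den <- den + abs(i * pr[i] - j * pr[j])
  busy <- if (den > 0) sum(pr * s) / den else 0
  cmplx <- 0; strength <- 0
  for (i in nz) for (j in nz) {
    if (i == j) next
    cmplx <- cmplx + abs(i - j) * (pr[i] * s[i] + pr[j] * s[j]) /
      (ntot * (pr[i] + pr[j]))
    strength <- strength + (pr[i] + pr[j]) * (i - j)^2
  }
  strength <- if (sum(s) > 0) strength / (eps + sum(s)) else 0
  c(ngtdm_coarseness = coarse, ngtdm_contrast = contrast,
    ngtdm_busyness = busy, ngtdm_complexity = cmplx,
    ngtdm_strength = strength)
}

# --- full 42-feature oracle (2-level images etc.) ---------------------------
oracle_texture_features <- function(q, ng, offsets = list(c(0L, 1L), c(1L, 0L),
                                                          c(1L, 1L), c(1L, -1L))) {
  glcm <- Reduce(`+`, lapply(offsets, function(o) {
    oracle_glcm_features(oracle_glcm(q, ng, o))
  })) / length(offsets)
  rl_names <- paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp",
                                 "lgle", "hgle", "sre_lgle", "sre_hgle",
                                 "lre_lgle", "lre_hgle", "glv", "rlv"))
  glrlm <- Reduce(`+`, lapply(offsets, function(o) {
    oracle_rl_features(oracle_glrlm(q, ng, o), length(q), rl_names)
  })) / length(offsets)
  sz_names <- paste0("glszm_", c("sze", "lze", "gln", "zsn", "zp",
                                 "lgle", "hgle", "sze_lgle", "sze_hgle",
                                 "lze_lgle", "lze_hgle", "glv", "zsv"))
  glszm <- oracle_rl_features(oracle_glszm(q, ng), length(q), sz_names)
  c(glcm, glrlm, glszm, oracle_ngtdm_features(q, ng))
}

# --- Minkowski oracle: loops + flood-fill Euler -----------------------------
oracle_area <- function(b) sum(b)

oracle_perimeter <- function(b) {
  n <- nrow(b); p <- ncol(b)
  tot <- 0
  for (r in 1:n) for (c in 1:p) {
    if (!b[r, c]) next
    for (s in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      rr <- r + s[1]; cc <- c + s[2]
      out <- rr < 1 || rr > n || cc < 1 || cc > p
      if (out || !b[rr, cc]) tot <- tot + 1
    }
  }
  tot
}

# count connected components of `cells` under the given neighbor set
oracle_n_components <- function(cells, nbrs) {
  if (nrow(cells) == 0) return(0)
  keys <- paste(cells[, 1], cells[, 2])
  seen <- rep(FALSE, nrow(cells))
  ncomp <- 0
  for (start in seq_len(nrow(cells))) {
    if (seen[start]) next
    ncomp <- ncomp + 1
    stack <- start; seen[start] <- TRUE
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      for (s in nbrs) {
        k <- paste(cells[cur, 1] + s[1], cells[cur, 2] + s[2])
        hit <- match(k, keys)
        if (!is.na(hit) && !seen[hit]) {
          seen[hit] <- TRUE; stack <- c(stack, hit)
        }
      }
    }
  }
  ncomp
}

# Euler = (#8-connected objects) - (#4-connected holes); holes are background
# components not touching the padded border
oracle_euler <- function(b) {
  n <- nrow(b); p <- ncol(b)
  nb8 <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
              c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  nb4 <- nb8[1:4]
  fg <- which(b, arr.ind = TRUE)
  pad <- matrix(FALSE, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- b
  bg <- which(!pad, arr.ind = TRUE)
  n_obj <- oracle_n_components(fg, nb8)
  # all background is 4-connected to the border frame, which is one component
  n_holes <- oracle_n_components(bg, nb4) - 1
  n_obj - n_holes
}

# --- NNLS by active-set enumeration (K <= 3) --------------------------------
oracle_nnls <- function(A, b) {
  k <- ncol(A)
  best <- list(x = numeric(k), rss = sum(b^2))
  subsets <- unlist(lapply(1:k, function(m) utils::combn(k, m, simplify = FALSE)),
                    recursive = FALSE)
  for (s in subsets) {
    z <- tryCatch(qr.coef(qr(A[, s, drop = FALSE]), b), error = function(e) NULL)
    if (is.null(z) || any(is.na(z)) || any(z < 0)) next
    x <- numeric(k); x[s] <- z
    rss <- sum((b - A %*% x)^2)
    if (rss < best$rss - 1e-12) best <- list(x = x, rss = rss)
  }
  best$x
}

# --- Welch t ----------------------------------------------------------------
oracle_welch_t <- function(a, b) {
  abs(mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
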