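# Independent layered Monte Carlo reference (MCML-style, plane-parallel
# geometry, infinite lateral extent), vectorized over photons. Used as the
# oracle for the voxel engine on slab problems; shares no code with the
# engine and uses R's own RNG.

hg_cos_vec <- function(g, xi) {
  iso <- abs(g) < 1e-12
  t <- (1 - g^2) / (1 - g + 2 * g * xi)
  out <- (1 + g^2 - t^2) / (2 * g)
  out[iso] <- (2 * xi - 1)[iso]
  out
}

fresnel_vec <- function(n1, n2, cosi) {
  cosi <- pmin(cosi, 1)
  sint2 <- (n1 / n2)^2 * (1 - cosi^2)
  tir <- sint2 >= 1
  cost <- sqrt(pmax(0, 1 - sint2))
  rs <- (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost)
  rp <- (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi)
  R <- 0.5 * (rs^2 + rp^2)
  R[tir] <- 1
  R[n1 == n2] <- 0
  cost[n1 == n2] <- cosi[n1 == n2]
  list(R = R, cost = cost)
}

mcml_layered <- function(layers, N, n_ambient = 1, seed = 1,
                         wth = 1e-4, chance = 0.1) {
  set.seed(seed)
  L <- nrow(layers)
  zb <- c(0, cumsum(layers$thickness))
  mua <- layers$mu_a; mus <- layers$mu_s; mut <- mua + mus
  gg <- layers$g; nn <- layers$n
  rsp <- ((n_ambient - nn[1]) / (n_ambient + nn[1]))^2
  w <- rep(1 - rsp, N); z <- rep(0, N); lay <- rep(1L, N)
  ux <- rep(0, N); uy <- rep(0, N); uz <- rep(1, N)
  alive <- rep(TRUE, N)
  sleft <- -log(runif(N))          # dimensionless step (mean free paths)
  Rd <- 0; Td <- 0; A <- 0
  it <- 0
  while (any(alive)) {
    it <- it + 1
    if (it > 2e5) stop("layered oracle failed to terminate")
    i <- which(alive)
    l <- lay[i]
    db <- rep(Inf, length(i))
    up <- uz[i] > 1e-12; dn <- uz[i] < -1e-12
    db[up] <- (zb[l[up] + 1L] - z[i[up]]) / uz[i[up]]
    db[dn] <- (zb[l[dn]] - z[i[dn]]) / uz[i[dn]]
    sphys <- sleft[i] / mut[l]
    hit <- db <= sphys

    j <- i[!hit]                   # interaction inside the layer
    if (length(j)) {
      lj <- lay[j]
      z[j] <- z[j] + uz[j] * sphys[!hit]
      dep <- w[j] * mua[lj] / mut[lj]
      A <- A + sum(dep)
      w[j] <- w[j] - dep
      ct <- hg_cos_vec(gg[lj], runif(length(j)))
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- 2 * pi * runif(length(j))
      cp <- cos(phi); sp <- sin(phi)
      uzj <- uz[j]; uxj <- ux[j]; uyj <- uy[j]
      near <- abs(uzj) > 0.99999
      den <- sqrt(pmax(1e-30, 1 - uzj^2))
      nx <- st * (uxj * uzj * cp - uyj * sp) / den + uxj * ct
      ny <- st * (uyj * uzj * cp + uxj * sp) / den + uyj * ct
      nz <- -st * cp * den + uzj * ct
      nx[near] <- (st * cp)[near]
      ny[near] <- (st * sp)[near]
      nz[near] <- (ct * sign(uzj))[near]
      nrm <- sqrt(nx^2 + ny^2 + nz^2)
      ux[j] <- nx / nrm; uy[j] <- ny / nrm; uz[j] <- nz / nrm
      sleft[j] <- -log(runif(length(j)))
      low <- which(w[j] < wth)
      if (length(low)) {
        jj <- j[low]
        surv <- runif(length(jj)) < chance
        A <- A + sum(w[jj][!surv])
        A <- A - sum(w[jj][surv] / chance - w[jj][surv])
        w[jj[surv]] <- w[jj[surv]] / chance
        w[jj[!surv]] <- 0
        alive[jj[!surv]] <- FALSE
      }
    }

    j <- i[hit]                    # boundary crossing
    if (length(j)) {
      lj <- lay[j]; dbj <- db[hit]
      z[j] <- z[j] + uz[j] * dbj
      sleft[j] <- sleft[j] - dbj * mut[lj]
      goingup <- uz[j] > 0
      nextl <- ifelse(goingup, lj + 1L, lj - 1L)
      inside <- nextl >= 1L & nextl <= L
      n1 <- nn[lj]
      n2 <- ifelse(inside, nn[pmin(pmax(nextl, 1L), L)], n_ambient)
      fr <- fresnel_vec(n1, n2, abs(uz[j]))
      refl <- runif(length(j)) < fr$R
      uz[j[refl]] <- -uz[j[refl]]
      tr <- which(!refl)
      if (length(tr)) {
        jt <- j[tr]
        sc <- n1[tr] / n2[tr]
        ux[jt] <- ux[jt] * sc; uy[jt] <- uy[jt] * sc
        uz[jt] <- sign(uz[jt]) * fr$cost[tr]
        nrm <- sqrt(ux[jt]^2 + uy[jt]^2 + uz[jt]^2)
        ux[jt] <- ux[jt] / nrm; uy[jt] <- uy[jt] / nrm; uz[jt] <- uz[jt] / nrm
        out <- !inside[tr]
        esc <- jt[out]
        if (length(esc)) {
          upe <- uz[esc] > 0
          Td <- Td + sum(w[esc][upe])
          Rd <- Rd + sum(w[esc][!upe])
          alive[esc] <- FALSE
          w[esc] <- 0
        }
        ins <- jt[!out]
        if (length(ins)) lay[ins] <- nextl[tr][!out]
      }
    }
  }
  list(Rd = Rd / N, Td = Td / N, A = A / N, Rsp = rsp, N = N)
}

# diffuse reflectance/transmittance of an engine slab run, with lateral loss
slab_summary <- function(run) {
  N <- run$n_launched
  wf <- tapply(run$escapes$w, run$escapes$face, sum)
  gv <- function(f) if (is.na(wf[f])) 0 else unname(wf[f])
  list(Rd = gv("z_min") / N, Td = gv("z_max") / N,
       A = run$absorbed / N,
       lateral = (gv("x_max") + gv("x_min") + gv("y_min") + gv("y_max")) / N)
}

# binomial-style standard error for a weight fraction
frac_se <- function(p, N) sqrt(pmax(p * (1 - p), 1e-12) / N)
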