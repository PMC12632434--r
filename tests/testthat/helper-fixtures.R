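# Shared fixture builders. Everything is generated in code at test time.

# water spectrum from a model, with optional additive noise (fraction
# of the peak), on the acquisition grid
make_water_spectrum <- function(model, temperature = 298, noise_sd = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nu <- seq(50, 550, by = 2)
  da <- eval_thz_model(model, nu)
  if (noise_sd > 0) da <- da + rnorm(length(nu), sd = noise_sd * max(da))
  structure(list(nu = nu, delta_alpha = da, phi_m = 0,
                 temperature = temperature, sample_id = "fixture"),
            class = "water_spectrum")
}

# frame of n random waters (random orientations) in a periodic cubic box
random_water_frame <- function(n, box_edge = 2, seed = 1,
                               temperature = 300) {
  set.seed(seed)
  pos <- vector("list", n); role <- character(0); mol <- integer(0)
  for (i in seq_len(n)) {
    o <- runif(3, 0, box_edge)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    a <- 104.5 * pi / 180
    pos[[i]] <- rbind(o, o + 0.1 * u, o + 0.1 * (cos(a) * u + sin(a) * v))
    role <- c(role, c("water_O", "water_H", "water_H"))
    mol <- c(mol, rep(i, 3L))
  }
  md_frame(do.call(rbind, pos), role, mol, rep(box_edge, 3),
           temperature = temperature)
}

# ideal linear water dimer: O-O separation d_OO along x, donor H on the
# axis; returns an md_frame in a generous periodic box
water_dimer_frame <- function(d_OO = 0.28, box_edge = 2) {
  o1 <- c(0.5, 1, 1)
  o2 <- o1 + c(d_OO, 0, 0)
  a <- 104.5 * pi / 180
  pos <- rbind(o1, o1 + c(0.1, 0, 0),
               o1 + 0.1 * c(cos(a), sin(a), 0),
               o2, o2 + 0.1 * c(cos(pi / 3), sin(pi / 3), 0),
               o2 + 0.1 * c(cos(pi / 3), -sin(pi / 3), 0))
  md_frame(pos, rep(c("water_O", "water_H", "water_H"), 2),
           rep(1:2, each = 3), rep(box_edge, 3))
}

# periodic square lattice of waters in one layer, spacing d, each
# donating along +x and +y: every water donates 2 and accepts 2
hb_lattice_frame <- function(n_side = 4, d = 0.28) {
  box <- c(n_side * d, n_side * d, 1)
  pos <- list(); mol <- integer(0)
  id <- 0L
  for (i in seq_len(n_side)) for (j in seq_len(n_side)) {
    id <- id + 1L
    o <- c((i - 1) * d, (j - 1) * d, 0.5)
    pos[[id]] <- rbind(o, o + c(0.1, 0, 0), o + c(0, 0.1, 0))
    mol <- c(mol, rep(id, 3L))
  }
  md_frame(do.call(rbind, pos), rep(c("water_O", "water_H", "water_H"),
                                    n_side^2), mol, box)
}
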