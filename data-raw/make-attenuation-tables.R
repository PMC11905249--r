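# Builds the photon interaction tables shipped in inst/extdata/attenuation/.
#
# Each element gets a TSV with columns
#   energy_keV  mu_total  mu_en  mu_pe  mu_incoh  mu_coh      (all cm^2/g)
# on a 1-150 keV grid, with duplicated rows at K absorption edges.
#
# Construction:
#  * mu_incoh is the free-electron Klein-Nishina cross section times Z/A
#    (the same model the transport engine samples from).
#  * total mass attenuation anchors for H, C, N, O, Al, Ca, Ti, I are
#    transcribed from standard published photon cross-section compilations;
#    mu_pe + mu_coh is defined as the anchored total minus Klein-Nishina.
#  * where classic mass energy-absorption anchors are available (H, C, Al,
#    water -> O), mu_pe is chosen so that mu_en = mu_pe*(1 - K-fluorescence
#    escape) + mu_incoh * f_KN reproduces them; elsewhere the coherent share
#    is modelled as R/(1+R), R = 0.25 * (8/Z)^1.3 * (E/30 keV).
#  * N is scaled from O (Z^4.5/A); trace elements (F, Na, Mg, P, S, Cl, Ar,
#    K) interpolate the per-mole photoelectric+coherent component in ln Z
#    between anchored neighbours.  L edges are smoothed; values below 8 keV
#    are approximate (transport cutoff region).
# Compound tables are Bragg-additive mixtures of the element tables.

suppressPackageStartupMessages(library(dplyr))

out_dir <- file.path("inst", "extdata", "attenuation")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## ---- Klein-Nishina helpers -------------------------------------------------

r_e <- 2.8179403e-13  # classical electron radius, cm
mec2 <- 511.0         # keV
NA_AVOG <- 6.02214076e23

kn_total_sigma <- function(E) {           # cm^2 per electron
  a <- E / mec2
  t1 <- (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a)
  t2 <- log(1 + 2 * a) / (2 * a)
  t3 <- (1 + 3 * a) / (1 + 2 * a)^2
  2 * pi * r_e^2 * (t1 + t2 - t3)
}

# mean fraction of photon energy transferred to the Compton electron
kn_transfer_fraction <- function(E) {
  a <- E / mec2
  mu_c <- seq(-1, 1, length.out = 4001)
  k <- 1 / (1 + a * (1 - mu_c))
  dsig <- k^2 * (k + 1 / k - (1 - mu_c^2))
  sum(dsig * (1 - k)) / sum(dsig)
}

## ---- element anchor data ---------------------------------------------------

# anchors: total mass attenuation (with coherent), cm^2/g
el <- list()
anchor <- function(E, v) data.frame(E = E, mu = v)

el$H <- list(Z = 1, A = 1.008, total = anchor(
  c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  c(7.217, 2.148, 1.059, 0.5612, 0.4546, 0.4193, 0.4042, 0.3914, 0.3854,
    0.3764, 0.3695, 0.3570, 0.3458, 0.3355, 0.3260, 0.3091, 0.2944, 0.2651)),
  muen = anchor(
    c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    c(0.00986, 0.0110, 0.0133, 0.0186, 0.0231, 0.0271, 0.0305, 0.0362,
      0.0406, 0.0481)))

el$C <- list(Z = 6, A = 12.011, total = anchor(
  c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  c(2211, 700.2, 303, 90.33, 37.78, 19.12, 10.95, 4.576, 2.373, 0.8071,
    0.4420, 0.2562, 0.2076, 0.1871, 0.1753, 0.1610, 0.1514, 0.1347)),
  muen = anchor(
    c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    c(2.078, 0.5627, 0.2238, 0.06614, 0.03343, 0.02397, 0.02098, 0.02037,
      0.02147, 0.02449)))

el$O <- list(Z = 8, A = 15.999, total = anchor(
  c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  c(4590, 1549, 694.9, 217.1, 93.15, 48.27, 27.70, 11.63, 5.952, 1.836,
    0.8651, 0.3779, 0.2585, 0.2132, 0.1907, 0.1678, 0.1551, 0.1361)))
# O mu_en derived below from the classic water anchors.

el$Al <- list(Z = 13, A = 26.982, edge = 1.5596, total = anchor(
  c(1, 1.5, 1.5596, 1.5596, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60,
    80, 100, 150),
  c(1185, 402.2, 362.1, 3957, 2263, 788.0, 360.5, 193.4, 115.3, 50.33,
    26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018, 0.1704,
    0.1378)),
  muen = anchor(
    c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    c(25.43, 7.487, 3.094, 0.8778, 0.3601, 0.1840, 0.1099, 0.05511,
      0.03794, 0.02827)))

el$Ca <- list(Z = 20, A = 40.078, edge = 4.0381,
  fluor = c(yield = 0.163, kalpha = 3.691), total = anchor(
  c(2, 3, 4.0381, 4.0381, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  c(730, 250, 118, 1026, 558, 340, 151, 93.41, 30.5, 14.46, 4.608, 2.190,
    1.203, 0.778, 0.411, 0.280, 0.170)))

el$Ti <- list(Z = 22, A = 47.867, edge = 4.9664,
  fluor = c(yield = 0.219, kalpha = 4.509), total = anchor(
  c(2, 3, 4, 4.9664, 4.9664, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  c(986, 324, 150, 83.8, 687.8, 432.3, 202.3, 110.7, 35.87, 15.85, 4.972,
    2.214, 1.213, 0.7661, 0.4052, 0.2721, 0.1649)))

el$I <- list(Z = 53, A = 126.904, edge = 33.1694,
  fluor = c(yield = 0.884, kalpha = 28.612), total = anchor(
  c(5, 6, 8, 10, 15, 20, 25, 30, 33.1694, 33.1694, 40, 50, 60, 80, 100, 150),
  c(900, 620, 300, 162, 55.2, 25.46, 14.1, 8.561, 6.553, 36.32, 22.41,
    12.32, 7.579, 3.510, 1.942, 0.6978)))

# classic water / air anchors (compound checks and O mu_en derivation)
water_muen <- anchor(
  c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  c(4.944, 1.374, 0.5503, 0.1557, 0.06947, 0.04223, 0.03190, 0.02597,
    0.02546, 0.02764))

loglog_interp <- function(E, tab) {
  # piecewise log-log interpolation with duplicated edge energies;
  # duplicated abscissae get an epsilon split so queries between branches work
  x <- log(tab$E)
  d <- duplicated(x)
  x[d] <- x[d] + 1e-9
  y <- log(tab$mu)
  exp(approx(x, y, xout = log(E), rule = 2)$y)
}

## ---- output energy grid ----------------------------------------------------

base_grid <- c(1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 10, 12, 15, 18, 20, 25, 28, 30,
               32, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 90, 100, 110, 120,
               130, 150)

element_grid <- function(e) {
  g <- base_grid
  if (!is.null(e$edge) && e$edge > min(g) && e$edge < max(g)) {
    g <- sort(unique(c(g[abs(g - e$edge) > 1e-6], e$edge, e$edge)))
    # keep duplicated edge rows
    g <- sort(c(g, e$edge))
    g <- g[!duplicated(paste(g, cumsum(g == e$edge)))]  # placeholder
  }
  g
}
# simpler: explicit duplication
element_grid <- function(e) {
  g <- base_grid
  if (!is.null(e$edge) && e$edge > 1 && e$edge < 150) {
    g <- sort(c(setdiff(g, e$edge), e$edge, e$edge))
  }
  g
}

## ---- decomposition ---------------------------------------------------------

escape_fraction <- function(e, E) {
  if (is.null(e$fluor)) return(rep(0, length(E)))
  ifelse(E > e$edge, e$fluor[["yield"]] * e$fluor[["kalpha"]] / E, 0)
}

coh_share_model <- function(Z, E) {
  R <- 0.25 * (8 / Z)^1.3 * (E / 30)
  R / (1 + R)
}

decompose_element <- function(e, grid, muen_anchor = NULL) {
  # handle edge sides: for duplicated energies, query epsilon below/above
  qE <- grid
  dup <- duplicated(grid)
  idx_edge <- which(grid %in% grid[dup])
  if (length(idx_edge)) {
    qE[idx_edge[1]] <- grid[idx_edge[1]] * (1 - 1e-7)
    qE[idx_edge[2]] <- grid[idx_edge[2]] * (1 + 1e-7)
  }
  total <- loglog_interp(qE, e$total)
  incoh <- kn_total_sigma(grid) * NA_AVOG * e$Z / e$A
  nonincoh <- pmax(total - incoh, 1e-8)
  fKN <- vapply(grid, kn_transfer_fraction, numeric(1))
  esc <- escape_fraction(e, grid)
  if (!is.null(muen_anchor)) {
    muen_t <- loglog_interp(qE, setNames(muen_anchor, c("E", "mu")))
    pe <- (muen_t - incoh * fKN) / (1 - esc)
    pe <- pmin(pmax(pe, 1e-8), nonincoh)
  } else {
    pe <- nonincoh * (1 - coh_share_model(e$Z, grid))
  }
  coh <- pmax(nonincoh - pe, 1e-8)
  muen <- pe * (1 - esc) + incoh * fKN
  data.frame(energy_keV = grid,
             mu_total = pe + incoh + coh,
             mu_en = muen,
             mu_pe = pe,
             mu_incoh = incoh,
             mu_coh = coh)
}

tables <- list()

tables$H  <- decompose_element(el$H,  element_grid(el$H),  el$H$muen)
tables$C  <- decompose_element(el$C,  element_grid(el$C),  el$C$muen)
tables$Al <- decompose_element(el$Al, element_grid(el$Al), el$Al$muen)

# O: mu_en from water anchors, removing the H contribution
wH <- 0.111894; wO <- 0.888106
muen_H_at <- loglog_interp(water_muen$E, setNames(el$H$muen, c("E", "mu")))
o_muen <- anchor(water_muen$E, (water_muen$mu - wH * muen_H_at) / wO)
tables$O <- decompose_element(el$O, element_grid(el$O), o_muen)

# N: photoelectric scaled from O by Z^4.5 / A, Klein-Nishina incoherent,
# coherent share model
make_scaled_element <- function(Z, A, ref_tab, ref_Z, ref_A, grid) {
  scale <- (Z / ref_Z)^4.5 * (ref_A / A)
  pe_ref <- loglog_interp(grid, data.frame(E = ref_tab$energy_keV,
                                           mu = ref_tab$mu_pe))
  pe <- pe_ref * scale
  incoh <- kn_total_sigma(grid) * NA_AVOG * Z / A
  fKN <- vapply(grid, kn_transfer_fraction, numeric(1))
  fc <- coh_share_model(Z, grid)
  coh <- pe * fc / (1 - fc)
  data.frame(energy_keV = grid, mu_total = pe + incoh + coh,
             mu_en = pe + incoh * fKN, mu_pe = pe, mu_incoh = incoh,
             mu_coh = coh)
}
tables$N <- make_scaled_element(7, 14.007, tables$O, 8, 15.999, base_grid)

# trace elements: per-mole photoelectric component interpolated in ln Z
anchored <- list(C = tables$C, O = tables$O, Al = tables$Al,
                 Ca = decompose_element(el$Ca, element_grid(el$Ca)),
                 Ti = decompose_element(el$Ti, element_grid(el$Ti)),
                 I  = decompose_element(el$I,  element_grid(el$I)))
tables$Ca <- anchored$Ca; tables$Ti <- anchored$Ti; tables$I <- anchored$I

anchor_Z <- c(C = 6, O = 8, Al = 13, Ca = 20, Ti = 22, I = 53)
anchor_A <- c(C = 12.011, O = 15.999, Al = 26.982, Ca = 40.078,
              Ti = 47.867, I = 126.904)

pe_molar_at <- function(name, E) {
  t <- anchored[[name]]
  loglog_interp(E, data.frame(E = t$energy_keV, mu = t$mu_pe)) * anchor_A[[name]]
}

make_interp_element <- function(Z, A, lo, hi, grid) {
  lnpe <- mapply(function(E) {
    y <- log(c(pe_molar_at(lo, E), pe_molar_at(hi, E)))
    x <- log(c(anchor_Z[[lo]], anchor_Z[[hi]]))
    approx(x, y, xout = log(Z))$y
  }, grid)
  pe <- exp(lnpe) / A
  incoh <- kn_total_sigma(grid) * NA_AVOG * Z / A
  fKN <- vapply(grid, kn_transfer_fraction, numeric(1))
  fc <- coh_share_model(Z, grid)
  coh <- pe * fc / (1 - fc)
  data.frame(energy_keV = grid, mu_total = pe + incoh + coh,
             mu_en = pe + incoh * fKN, mu_pe = pe, mu_incoh = incoh,
             mu_coh = coh)
}

tables$F  <- make_interp_element(9, 18.998, "O", "Al", base_grid)
tables$Na <- make_interp_element(11, 22.990, "O", "Al", base_grid)
tables$Mg <- make_interp_element(12, 24.305, "O", "Al", base_grid)
tables$P  <- make_interp_element(15, 30.974, "Al", "Ca", base_grid)
tables$S  <- make_interp_element(16, 32.06, "Al", "Ca", base_grid)
tables$Cl <- make_interp_element(17, 35.45, "Al", "Ca", base_grid)
tables$Ar <- make_interp_element(18, 39.948, "Al", "Ca", base_grid)
tables$K  <- make_interp_element(19, 39.098, "Al", "Ca", base_grid)

## ---- compound tables -------------------------------------------------------

compositions <- list(
  water         = c(H = 0.111894, O = 0.888106),
  air           = c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827),
  pmma          = c(H = 0.080538, C = 0.599848, O = 0.319614),
  teflon        = c(C = 0.240183, F = 0.759817),
  soft_tissue   = c(H = 0.102, C = 0.143, N = 0.034, O = 0.708, Na = 0.002,
                    P = 0.003, S = 0.003, Cl = 0.002, K = 0.003),
  lung          = c(H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002,
                    P = 0.002, S = 0.003, Cl = 0.003, K = 0.002),
  cortical_bone = c(H = 0.034, C = 0.155, N = 0.042, O = 0.435, Na = 0.001,
                    Mg = 0.002, P = 0.103, S = 0.003, Ca = 0.225)
)

interp_col <- function(tab, col, E) {
  x <- log(tab$energy_keV); d <- duplicated(x); x[d] <- x[d] + 1e-9
  exp(approx(x, log(pmax(tab[[col]], 1e-12)), xout = log(E), rule = 2)$y)
}

compound_table <- function(w) {
  grid <- sort(unique(unlist(lapply(names(w), function(s) tables[[s]]$energy_keV))))
  # keep duplicated edges of member elements
  dups <- unlist(lapply(names(w), function(s) {
    e <- tables[[s]]$energy_keV; e[duplicated(e)]
  }))
  grid <- sort(c(grid, dups))
  cols <- c("mu_total", "mu_en", "mu_pe", "mu_incoh", "mu_coh")
  out <- data.frame(energy_keV = grid)
  qE <- grid
  for (d in unique(dups)) {
    i <- which(grid == d)
    qE[i[1]] <- d * (1 - 1e-7); qE[i[2]] <- d * (1 + 1e-7)
  }
  for (col in cols) {
    acc <- 0
    for (s in names(w)) acc <- acc + w[[s]] * interp_col(tables[[s]], col, qE)
    out[[col]] <- acc
  }
  out
}

for (nm in names(compositions)) tables[[nm]] <- compound_table(compositions[[nm]])

## ---- write -----------------------------------------------------------------

fmt <- function(x) formatC(x, digits = 6, format = "g")
for (nm in names(tables)) {
  t <- tables[[nm]]
  t[] <- lapply(t, fmt)
  write.table(t, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

manifest <- data.frame(
  table = names(tables),
  rows = vapply(tables, nrow, integer(1)),
  version = "1"
)
write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- sanity printout -------------------------------------------------------

chk <- function(nm, E, col = "mu_total") {
  t <- tables[[nm]]
  v <- interp_col(t, col, E)
  cat(sprintf("%-14s %6.2f keV  %-9s %.5g\n", nm, E, col, v))
}
chk("Al", 60); chk("water", 60); chk("water", 60, "mu_en")
chk("air", 60); chk("air", 60, "mu_en"); chk("pmma", 60)
chk("I", 40); chk("I", 40, "mu_en"); chk("cortical_bone", 60)
rho_al <- 2.699
for (hvl in c(9.2, 9.4)) {
  mu <- log(2) / (hvl / 10 * rho_al)
  tAl <- tables$Al
  x <- log(as.numeric(0) + tAl$energy_keV); y <- log(tAl$mu_total)
  Eeff <- exp(approx(y[order(y)], x[order(y)], xout = log(mu))$y)
  cat(sprintf("HVL %.1f mm -> mu/rho %.5f -> E_eff %.2f keV\n", hvl, mu, Eeff))
}
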