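# shared in-code fixtures for the suite; everything is built at test time

# three heavy atoms on a line plus one hydrogen, handy for RMSD checks
tri_mol <- function(name = "tri", shift = c(0, 0, 0)) {
  molecule(name,
           c("C", "C", "C", "H"),
           rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0.5, 0.9, 0)) +
             rep(shift, each = 4),
           charges = c(-0.1, 0.0, 0.1, 0.0))
}

# rigid benzene-like hexagon (carbons only)
hexagon_mol <- function(name = "hex") {
  xyz <- t(sapply(0:5, function(k)
    c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)))
  molecule(name, rep("C", 6), xyz)
}

# a single atom with a charge, for field identities
atom_mol <- function(element = "C", charge = 0, at = c(0, 0, 0)) {
  molecule("atom", element, matrix(at, 1), charges = charge)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "mifqsar")
  if (!nzchar(path)) stop("missing packaged fixture ", file)
  path
}

# printed docking-accuracy reference rows for the packaged RCCD fixtures (%)
table5_da_printed <- c(
  "AutoDock" = 21.43, "Vina" = 50.00, "SMINA/vina" = 35.71,
  "SMINA/vinardo" = 35.71, "SMINA/ad4" = 28.57, "DOCK" = 28.57,
  "PLANTS/plp95" = 32.14)
table6_da_printed <- c(
  "AutoDock" = 31.82, "Vina" = 63.64, "SMINA/vina" = 45.45,
  "SMINA/vinardo" = 45.45, "SMINA/ad4" = 36.36, "DOCK" = 18.18,
  "PLANTS/chemplp" = 40.91, "PLANTS/plp" = 36.36)
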