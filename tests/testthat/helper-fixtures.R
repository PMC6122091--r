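# Fixture builders shared across the suite.  Everything is generated in
# code; files are written to withr-style temp paths inside each test.

three_state_stick <- function()
  StickSpectrum(c(4.5, 5.2, 6.0), c(8, -15, -10), label = "fixture-3state")

# Gaussian-type TDDFT log dialect: "Excited State" lines plus an R(length)
# rotatory-strength table.
make_qc_log_lines <- function(energies, rstrengths,
                              f = rep(0.01, length(energies)),
                              spin = "Singlet-A",
                              r_rows = seq_along(energies)) {
  n <- length(energies)
  nm <- 1239.841984 / energies
  header <- c(
    " Excitation energies and oscillator strengths:",
    "")
  es <- unlist(lapply(seq_len(n), function(i) c(
    sprintf(" Excited State %3d:      %s     %7.4f eV  %7.2f nm  f=%.4f  <S**2>=0.000",
            i, spin, energies[i], nm[i], f[i]),
    sprintf("     %3d -> %3d        0.70000", 10 + i, 20 + i),
    "")))
  rtab <- c(
    "                    1/2[<0|r|b>*<b|rxdel|0> + (<0|rxdel|b>*<b|r|0>)*]",
    "                    Rotatory Strengths (R) in cgs (10**-40 erg-esu-cm/Gauss)",
    "       state          XX          YY          ZZ     R(length)",
    sprintf("       %5d    %10.4f  %10.4f  %10.4f  %10.4f",
            r_rows, 0.1 * r_rows, -0.2 * r_rows, 0.3 * r_rows,
            rstrengths[r_rows]),
    "",
    " SavETr:  write IOETrn=   770 NScale= 10")
  c(header, es, rtab)
}

write_qc_log <- function(path, energies = c(4.50, 5.20, 6.00),
                         rstrengths = c(8.0, -15.0, -10.0), ...) {
  writeLines(make_qc_log_lines(energies, rstrengths, ...), path)
  path
}

# --- molecular fixtures -------------------------------------------------

.pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                           element, record = "ATOM  ") {
  namefield <- if (nchar(name) >= 4) sprintf("%-4s", name)
               else sprintf(" %-3s", name)
  sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namefield, resname, chain, resid, x, y, z,
          1, 0, element)
}

# One synthetic guanine deoxynucleotide (approximate but chemically sane
# geometry: planar base, sugar ring, phosphate).
guanine_nucleotide_atoms <- function(with_backbone = TRUE) {
  base <- data.frame(
    name = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3",
             "C4", "H8", "H1", "H21", "H22"),
    x = c(0.000, 1.370, 2.020, 1.120, 1.290, 2.350, 0.110, -1.110, -2.190,
          -1.290, -0.140, 1.840, 0.150, -3.080, -2.090),
    y = c(0.000, 0.060, -1.080, -2.080, -3.470, -4.080, -4.160, -3.590,
          -4.370, -2.280, -1.540, 1.030, -5.160, -3.940, -5.370),
    z = 0)
  bb <- data.frame(
    name = c("C1'", "O4'", "C2'", "C3'", "O3'", "C4'", "C5'", "O5'",
             "P", "OP1", "OP2", "H1'", "H2'", "H2''", "H3'", "H4'",
             "H5'", "H5''"),
    x = c(-0.760, -2.100, -0.400, -1.650, -1.700, -2.800, -3.900, -5.000,
          -6.300, -7.300, -6.100, -0.600, 0.560, -0.350, -1.700, -3.200,
          -4.250, -3.550),
    y = c(1.200, 1.050, 2.480, 3.340, 4.400, 2.350, 2.500, 1.650, 1.700,
          0.800, 1.400, 1.300, 2.900, 2.300, 3.750, 2.400, 3.540, 2.250),
    z = c(0.550, 0.300, -0.200, 0.000, -0.930, -0.200, 0.830, 0.500, 1.400,
          0.800, 2.840, 1.630, 0.100, -1.280, 1.010, -1.210, 0.830, 1.840))
  at <- if (with_backbone) rbind(base, bb) else base
  at$element <- sub("^([A-Za-z]).*$", "\\1", at$name)
  at
}

write_guanine_pdb <- function(path, with_backbone = TRUE, chain = "A",
                              resid = 1, shift = c(0, 0, 0),
                              resname = "DG") {
  at <- guanine_nucleotide_atoms(with_backbone)
  lines <- vapply(seq_len(nrow(at)), function(i)
    .pdb_atom_line(i, at$name[i], resname, chain, resid,
                   at$x[i] + shift[1], at$y[i] + shift[2], at$z[i] + shift[3],
                   at$element[i]), character(1))
  writeLines(c(lines, "END"), path)
  path
}

# A G2-Ag2-G2-like fixture: four guanine nucleotides on two chains plus two
# silver ions between them.
write_tetramer_pdb <- function(path) {
  lines <- character()
  serial <- 0
  add_res <- function(chain, resid, shift) {
    at <- guanine_nucleotide_atoms(TRUE)
    vapply(seq_len(nrow(at)), function(i) {
      serial <<- serial + 1
      .pdb_atom_line(serial, at$name[i], "DG", chain, resid,
                     at$x[i] + shift[1], at$y[i] + shift[2],
                     at$z[i] + shift[3], at$element[i])
    }, character(1))
  }
  lines <- c(add_res("A", 1, c(0, 0, 0)),
             add_res("A", 2, c(0, 0, 3.4)),
             add_res("B", 1, c(8, 0, 0)),
             add_res("B", 2, c(8, 0, 3.4)))
  ag <- c(.pdb_atom_line(length(lines) + 1, "AG", "AG", "C", 1,
                         4.0, -1.0, 0.0, "Ag", record = "HETATM"),
          .pdb_atom_line(length(lines) + 2, "AG", "AG", "C", 2,
                         4.0, -1.0, 3.4, "Ag", record = "HETATM"))
  writeLines(c(lines, ag, "END"), path)
  path
}
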