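# in-code fixture builders shared across the suite

# tiny two-residue amide table
tiny_table <- function(h = c(8.20, 7.95), n = c(119.0, 121.3),
                       residues = c(782L, 783L),
                       types = c("N", "I"), label = "pt") {
  shift_table(rep(residues, each = 2), rep(types, each = 2),
              rep(c("H", "N"), length(residues)),
              as.vector(rbind(h, n)), point_label = label)
}

# minimal NMR-STAR v3 assigned-chemical-shift fixture
star_fixture <- function(path, malformed = FALSE) {
  val_h1 <- if (malformed) "8.2a" else "8.25"
  writeLines(c(
    "data_synthetic_test",
    "save_assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Seq_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    paste("      1 1 MET H ", val_h1),
    "      2 1 MET N  119.20",
    "      3 2 HIS H  7.90",
    "      4 2 HIS N  121.00",
    "      5 2 HIS CD2 119.00",
    "      6 2 HIS CE1 139.00",
    "      7 2 HIS CA  56.10",
    "   stop_",
    "save_"
  ), path)
  path
}

# minimal N/CA/C backbone PDB written in fixed-width format; one chain,
# one residue type per residue number
write_toy_pdb <- function(path, resnos, types = NULL) {
  if (is.null(types)) types <- rep("ALA", length(resnos))
  types <- toupper(types)
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(resnos)) {
    for (at in c("N", "CA", "C")) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, at, types[i], resnos[i],
        i * 3.8, 0, 0, 1.00, 0.00, substr(at, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

aa3 <- function(x) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  unname(tab[toupper(x)])
}

# noiseless/noisy simulated series with a handful of binders; small and
# fast, used wherever a full titration is needed
small_sim <- function(seed = 1, noise_H = 0, noise_N = 0, loss = 0,
                      kd = 100, n_residues = 20,
                      binder_res = 15:18,
                      L = c(0, 50, 100, 200, 400, 800), P = 300) {
  spec <- titration_spec(
    n_residues = n_residues,
    binders = data.frame(residue_number = binder_res,
                         dmax_H = seq(0.05, 0.12,
                                      length.out = length(binder_res)),
                         dmax_N = 4 * seq(0.05, 0.12,
                                          length.out = length(binder_res))),
    kd = kd, P_conc = P, L_schedule = L,
    noise_sd_H = noise_H, noise_sd_N = noise_N,
    peak_loss_prob = loss, seed = seed)
  simulate_titration(spec)
}
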