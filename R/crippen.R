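# Wildman & Crippen (1999) atomic contributions to logP and molar
# refractivity. Types are assigned by graph rules mirroring the published
# SMARTS definitions in their original priority order; blank MR entries in
# the published table are taken as 0.
.crippen_params <- local({
  m <- rbind(
    C1 = c(0.1441, 2.503), C2 = c(0, 2.433), C3 = c(-0.2035, 2.753),
    C4 = c(-0.2051, 2.731), C5 = c(-0.2783, 5.007), C6 = c(0.1551, 3.513),
    C7 = c(0.0017, 3.888), C8 = c(0.08452, 2.464), C9 = c(-0.1444, 2.412),
    C10 = c(-0.0516, 2.488), C11 = c(0.1193, 2.582), C12 = c(-0.0967, 2.576),
    C13 = c(-0.5443, 4.041), C14 = c(0, 3.257), C15 = c(0.245, 3.564),
    C16 = c(0.198, 3.18), C17 = c(0, 3.104), C18 = c(0.1581, 3.35),
    C19 = c(0.2955, 4.346), C20 = c(0.2713, 3.904), C21 = c(0.136, 3.509),
    C22 = c(0.4619, 4.067), C23 = c(0.5437, 3.853), C24 = c(0.1893, 2.673),
    C25 = c(-0.8186, 3.135), C26 = c(0.264, 4.305), C27 = c(0.2148, 2.693),
    CS = c(0.08129, 3.243),
    H1 = c(0.123, 1.057), H2 = c(-0.2677, 1.395), H3 = c(0.2142, 0.9627),
    H4 = c(0.298, 1.805), HS = c(0.1125, 1.112),
    N1 = c(-1.019, 2.262), N2 = c(-0.7096, 2.173), N3 = c(-1.027, 2.827),
    N4 = c(-0.5188, 3), N5 = c(0.08387, 1.757), N6 = c(0.1836, 2.428),
    N7 = c(-0.3187, 1.839), N8 = c(-0.4458, 2.819), N9 = c(0.01508, 1.725),
    N10 = c(-1.95, 0), N11 = c(-0.3239, 2.202), N12 = c(-1.119, 0),
    N13 = c(-0.3396, 0.2604), N14 = c(0.2887, 3.359), NS = c(-0.4806, 2.134),
    O1 = c(0.1552, 1.08), O2 = c(-0.2893, 0.8238), O3 = c(-0.0684, 1.085),
    O4 = c(-0.4195, 1.182), O5 = c(0.0335, 3.367), O6 = c(-0.3339, 0.7774),
    O7 = c(-1.189, 0), O8 = c(0.1788, 3.135), O9 = c(-0.1526, 0),
    O10 = c(0.1129, 0.2215), O11 = c(0.4833, 0.389), O12 = c(-1.326, 0),
    OS = c(-0.1188, 0.6865),
    F = c(0.4202, 1.108), Cl = c(0.6895, 5.853), Br = c(0.8456, 8.927),
    I = c(0.8857, 14.02), Hal = c(-2.996, 0),
    P = c(0.8612, 6.92),
    S1 = c(0.6482, 7.591), S2 = c(-0.0024, 7.365), S3 = c(0.6237, 6.691),
    Me1 = c(-0.3808, 5.754), Me2 = c(-0.0025, 0)
  )
  colnames(m) <- c("logp", "mr")
  m
})

.crippen_het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

# per-atom context used by the typer
.crippen_ctx <- function(mol) {
  n <- n_atoms(mol)
  nbr <- vector("list", n); ord <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    o <- if (isTRUE(mol$bonds$aromatic[k])) 1.5 else mol$bonds$order[k]
    nbr[[i]] <- c(nbr[[i]], j); ord[[i]] <- c(ord[[i]], o)
    nbr[[j]] <- c(nbr[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nbr = nbr, ord = ord)
}

# classify one heavy atom; returns a type name in .crippen_params
crippen_atom_type <- function(mol, a, ctx) {
  at <- mol$atoms
  el <- at$element[a]; ar <- isTRUE(at$aromatic[a])
  h <- at$h_count[a]; chg <- at$charge[a]
  nb <- ctx$nbr[[a]]; oo <- ctx$ord[[a]]
  deg <- length(nb)
  X <- deg + h                               # total connections
  nel <- at$element[nb]; nar <- at$aromatic[nb]
  sp3 <- all(oo == 1)                         # all single bonds
  dbl <- nb[oo == 2]                          # double-bond partners
  trp <- nb[oo == 3]
  ali <- !nar                                 # aliphatic neighbor mask
  n_arom_bond <- sum(oo == 1.5)

  if (el == "C") {
    if (!ar) {
      allC_ali <- deg == 0 || all(nel == "C" & ali)
      if (sp3) {
        if ((h == 4 && deg == 0) || (h == 3 && deg == 1 && allC_ali) ||
            (h == 2 && deg == 2 && allC_ali)) return("C1")
        if ((h == 1 && deg == 3 && allC_ali) ||
            (h == 0 && deg == 4 && allC_ali)) return("C2")
        het_ali <- nel %in% .crippen_het & ali
        if (h == 3 && deg == 1 && het_ali[1]) return("C3")
        if (h == 2 && X == 4 && any(het_ali) && all(ali)) return("C3")
        if (h == 1 && X == 4 && any(het_ali) && all(ali)) return("C4")
        if (h == 0 && X == 4 && any(het_ali) && all(ali)) return("C4")
      }
      if (length(dbl) && any(nel[match(dbl, nb)] != "C" & !nar[match(dbl, nb)]))
        return("C5")
      dblC_ali <- dbl[at$element[dbl] == "C" & !at$aromatic[dbl]]
      if (length(dblC_ali)) {
        others <- setdiff(nb, dblC_ali[1])
        if (all(!at$aromatic[others])) return("C6")
        return("C26")
      }
      if (length(trp) && X == 2) return("C7")
      if (h == 3 && deg == 1 && nar[1]) {
        return(if (nel[1] == "C") "C8" else "C9")
      }
      if (sp3 && h == 2 && any(nar)) return("C10")
      if (sp3 && h == 1 && X == 4 && any(nar)) return("C11")
      if (sp3 && h == 0 && X == 4 && any(nar)) return("C12")
      dblc <- dbl[at$aromatic[dbl]]
      if (length(dblc)) return("C26")
      if (sp3 && any(!(nel %in% c("C", .crippen_het)) & ali)) return("C27")
      return("CS")
    } else {
      single_nb <- nb[oo == 1]
      if (h == 0 && length(single_nb)) {
        s_el <- at$element[single_nb]; s_ar <- at$aromatic[single_nb]
        if (any(!s_ar & !(s_el %in% c("C", "N", "O", "S", .crippen_het))))
          return("C13")
        if (any(s_el == "F")) return("C14")
        if (any(s_el == "Cl")) return("C15")
        if (any(s_el == "Br")) return("C16")
        if (any(s_el == "I")) return("C17")
      }
      if (h >= 1) return("C18")
      if (n_arom_bond >= 3) return("C19")
      if (length(single_nb) && any(at$aromatic[single_nb])) return("C20")
      if (length(single_nb)) {
        s_el <- at$element[single_nb]
        if (any(s_el == "C")) return("C21")
        if (any(s_el == "N")) return("C22")
        if (any(s_el == "O")) return("C23")
        if (any(s_el == "S")) return("C24")
      }
      if (length(dbl) && any(at$element[dbl] %in% c("C", "N", "O")))
        return("C25")
      return("CS")
    }
  }

  if (el == "N") {
    if (ar) return(if (chg > 0) "N12" else "N11")
    if (chg > 0 && h >= 1) return("N10")
    if (chg == 0) {
      if (h == 2 && deg == 1 && !nar[1]) return("N1")
      if (h == 1 && deg == 2 && sp3 && all(ali)) return("N2")
      if (h == 2 && deg == 1 && nar[1]) return("N3")
      if (h == 1 && deg == 2 && sp3 && any(nar)) return("N4")
      if (h == 1 && length(dbl)) return("N5")
      if (h == 0 && length(dbl) == 1 && deg == 2) return("N6")
      if (h == 0 && deg == 3 && sp3 && all(ali)) return("N7")
      if (h == 0 && deg == 3 && sp3 && any(nar)) return("N8")
      if (length(trp)) return("N9")
      return("NS")
    }
    if (chg > 0 && h == 0 && (deg == 4 || (deg == 3 && length(dbl) == 1)))
      return("N13")
    return("N14")
  }

  if (el == "O") {
    if (ar) return("O1")
    if (h >= 1 && chg == 0) return("O2")
    if (chg == 0 && deg == 2 && sp3) {
      return(if (any(nar)) "O4" else "O3")
    }
    if (length(dbl) == 1 || (chg < 0 && deg == 1)) {
      p <- if (length(dbl)) dbl[1] else nb[1]
      pel <- at$element[p]; par <- at$aromatic[p]
      if (pel %in% c("N", "O")) return("O5")
      if (pel == "S") return("O6")
      if (chg < 0 && pel == "C") {
        # carboxylate: partner carbon also double-bonded to an O
        pnb <- ctx$nbr[[p]]; pord <- ctx$ord[[p]]
        if (any(at$element[pnb[pord == 2]] == "O")) return("O12")
      }
      if (chg < 0) return("O7")
      if (par) return("O8")
      if (pel == "C") {
        others <- setdiff(ctx$nbr[[p]], a)
        o_el <- at$element[others]; o_ar <- at$aromatic[others]
        ph <- at$h_count[p]
        if (any(o_ar)) return("O10")
        if (ph >= 1) return("O9")                    # O=CH-, O=CH2
        if (any(o_el == "C")) return("O9")           # O=C(C)(A)
        if (length(others) == 2 && !any(o_el == "C")) return("O11")
        return("O9")                                 # O=C=O and kin
      }
    }
    return("OS")
  }

  if (el %in% c("F", "Cl", "Br", "I")) {
    return(if (chg == 0) el else "Hal")
  }
  if (el == "P") return("P")
  if (el == "S") {
    if (ar) return("S3")
    if (chg != 0 || any(at$element[dbl] %in% c("N", "O", "P", "S"))) return("S2")
    return("S1")
  }
  warn(sprintf("no Crippen type for element %s; using metal wildcard", el))
  "Me1"
}

# type for an implicit hydrogen attached to heavy atom a
crippen_h_type <- function(mol, a, ctx) {
  el <- mol$atoms$element[a]
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    nb <- setdiff(ctx$nbr[[a]], integer(0))
    if (length(nb) == 0) return("HS")                       # water
    p <- nb[1]
    pel <- mol$atoms$element[p]; par <- mol$atoms$aromatic[p]
    if (pel == "N") return("H3")
    if (pel %in% c("O", "S")) return("H4")
    if (pel == "C") {
      pord <- ctx$ord[[p]]; pnb <- ctx$nbr[[p]]
      if (any(pord == 2 & mol$atoms$element[pnb] %in% c("C", "N", "O", "S")))
        return("H4")                                        # acid-like O-H
      return("H2")                                          # alcohol / phenol
    }
    return("H2")
  }
  if (el %in% c("S")) return("H2")
  "HS"
}

#' Wildman-Crippen atomic logP and molar refractivity contributions
#'
#' Assigns every heavy atom a Wildman-Crippen atom type by graph rules and
#' returns its logP and MR contributions with the attached-hydrogen
#' contributions folded in. Summing each column gives the whole-molecule
#' Crippen logP and MR.
#'
#' @param mol A [mol_graph()].
#' @return A tibble with one row per heavy atom: `type`, `slogp`, `smr`.
#' @export
compute_crippen_contributions <- function(mol) {
  ctx <- .crippen_ctx(mol)
  n <- n_atoms(mol)
  types <- character(n); slogp <- numeric(n); smr <- numeric(n)
  for (a in seq_len(n)) {
    ty <- crippen_atom_type(mol, a, ctx)
    types[a] <- ty
    slogp[a] <- .crippen_params[ty, "logp"]
    smr[a] <- .crippen_params[ty, "mr"]
    hnum <- mol$atoms$h_count[a]
    if (hnum > 0) {
      hty <- crippen_h_type(mol, a, ctx)
      slogp[a] <- slogp[a] + hnum * .crippen_params[hty, "logp"]
      smr[a] <- smr[a] + hnum * .crippen_params[hty, "mr"]
    }
  }
  tibble(type = types, slogp = slogp, smr = smr)
}
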