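# independent brute-force proteoform enumeration: explicit nested recursion,
# no shared code with enumerate_proteoforms()/site_convolution()
brute_force_proteoforms <- function(protein, table = monosaccharide_masses()) {
  site_lists <- lapply(protein$sites, function(s) {
    ab <- vapply(s$isoforms, function(i) i$abundance, numeric(1))
    m <- vapply(s$isoforms, function(iso) {
      if (!is.null(iso$delta_da)) iso$delta_da
      else composition_mass(iso$composition, table)
    }, numeric(1))
    list(m = m, p = ab / sum(ab))
  })
  res_mass <- numeric(0)
  res_p <- numeric(0)
  rec <- function(i, mass, prob) {
    if (i > length(site_lists)) {
      res_mass <<- c(res_mass, mass)
      res_p <<- c(res_p, prob)
      return(invisible())
    }
    for (j in seq_along(site_lists[[i]]$m))
      rec(i + 1L, mass + site_lists[[i]]$m[j], prob * site_lists[[i]]$p[j])
  }
  rec(1L, protein$backbone_mass, 1)
  data.frame(total_mass = res_mass, probability = res_p)
}

# independent merge for the oracle route: sort, group by gap > tol, sum
oracle_merge <- function(mass, prob, tol) {
  ord <- order(mass)
  mass <- mass[ord]; prob <- prob[ord]
  grp <- cumsum(c(1, as.integer(diff(mass) > tol)))
  data.frame(
    mass = as.numeric(tapply(mass * prob, grp, sum)) /
      as.numeric(tapply(prob, grp, sum)),
    abundance = as.numeric(tapply(prob, grp, sum)))
}

# random small protein model for property tests
random_model <- function(seed, n_sites = 3, max_iso = 3) {
  set.seed(seed)
  sites <- lapply(seq_len(n_sites), function(i) {
    k <- sample(seq_len(max_iso), 1)
    isoforms <- lapply(seq_len(k), function(j) {
      comp <- c(Hex = sample(0:5, 1), HexNAc = sample(0:4, 1),
                Sia = sample(0:3, 1))
      mod_isoform(paste0("i", j), glycan_composition(comp),
                  abundance = stats::runif(1, 0.1, 5))
    })
    site_table(paste0("S", i), isoforms)
  })
  protein_model("rand", stats::runif(1, 5000, 30000), sites)
}

# hand-built model whose modal proteoform carries exactly 13 sialic acids
# (3 tetra-sialylated N-glycans + 1 mono-sialylated O-core), as on rhEPO
modal_sia13_model <- function() {
  nsite <- function(id) site_table(id, list(
    mod_isoform("A4S4", "Hex7HexNAc6Fuc1Sia4", abundance = 10),
    mod_isoform("A4S3", "Hex7HexNAc6Fuc1Sia3", abundance = 2),
    mod_isoform("A2S2", "Hex5HexNAc4Sia2", abundance = 1)
  ), kind = "N")
  osite <- site_table("S126", list(
    mod_isoform("core1S1", "Hex1HexNAc1Sia1", abundance = 8),
    mod_isoform("core1S2", "Hex1HexNAc1Sia2", abundance = 2)
  ), kind = "O")
  protein_model("modal13",
                backbone_mass_from_sequence(rhepo_sequence(), 2),
                list(nsite("N24"), nsite("N38"), nsite("N83"), osite))
}

modal_mass <- function(zc) zc$mass[which.max(zc$abundance)]
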