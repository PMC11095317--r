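## Residue group tables for the composition/transition/distribution (CTD)
## descriptors: 13 physicochemical properties, each partitioning the 20
## canonical residues into 3 disjoint groups (hence 13 x 21 = 273 features).
## Groupings follow the published descriptor-suite tables (seven
## hydrophobicity scales plus van der Waals volume, polarity,
## polarizability, charge, secondary structure and solvent accessibility).
## Table version: ctd-groups-v1.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CTD_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN",     "GASTPHY",          "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE",    "RAHCKMV",          "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV",            "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT",   "GRHA",             "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV",           "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP",  "SGTAW",            "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD",     "NTPG",             "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC",    "NVEQIL",           "MHKFRYW"),
  polarity                  = c("LIFWCMVY",   "PATGS",            "HQRKNED"),
  polarizability            = c("GASDT",      "CPNVEQIL",         "KMHFRYW"),
  charge                    = c("KR",         "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct           = c("EALMQKRH",   "VIYCWFT",          "GNPSD"),
  solventaccess             = c("ALFCGIVW",   "RKQEND",           "MSPTHY")
)

## Conjoint-triad classes: the standard 7-way residue grouping by dipole and
## side-chain volume; 7^3 = 343 class triples.
CTRIAD_CLASSES <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")

## residue -> group index lookup per CTD property (named integer vectors)
.ctdLookup <- lapply(CTD_GROUPS, function(groups) {
  lut <- integer(0)
  for (g in seq_along(groups)) {
    res <- strsplit(groups[[g]], "")[[1]]
    lut[res] <- g
  }
  lut[AA_ALPHABET]
})

## residue -> conjoint class index lookup
.ctriadLookup <- local({
  lut <- integer(0)
  for (g in seq_along(CTRIAD_CLASSES)) {
    res <- strsplit(CTRIAD_CLASSES[[g]], "")[[1]]
    lut[res] <- g
  }
  lut[AA_ALPHABET]
})
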