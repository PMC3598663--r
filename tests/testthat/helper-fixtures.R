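# Shared fixtures built in code.

# Published homolog marginals of the Aroclor 1260 control and of the most
# extensively dechlorinated culture (mol% of total PCBs), as homolog-level
# profiles at the nominal 81 uM mixture concentration.
control_homolog_profile <- function() {
  congenerProfile(c("tri-CB" = 0.07, "tetra-CB" = 0.21, "penta-CB" = 9.63,
                    "hexa-CB" = 47.75, "hepta-CB" = 36.26, "octa-CB" = 5.51,
                    "nona-CB" = 0.57),
                  totalConc = 81, label = "Aroclor 1260 control")
}

dechlorinated_homolog_profile <- function() {
  congenerProfile(c("tri-CB" = 1.18, "tetra-CB" = 26.93, "penta-CB" = 21.20,
                    "hexa-CB" = 19.52, "hepta-CB" = 25.22, "octa-CB" = 5.39,
                    "nona-CB" = 0.56),
                  totalConc = 81, label = "dechlorinated, 3 months")
}

# Loss/gain congener lists of the culture whose pattern matches Process H
# (flanked para + doubly flanked meta removal).
cw4_losses <- function() c("245-245-CB", "234-245-CB", "2345-245-CB",
                           "2345-236-CB", "2345-25-CB", "2345-234-CB")
cw4_gains <- function() c("25-25-CB", "235-25-CB", "24-25-CB", "2345-26-CB")

# Independent mirror-normalization used by enumeration oracles: of the 8
# symmetry-equivalent renderings of a ring pair (2 mirrors per ring x 2 ring
# orders), take the lexicographically smallest "a|b" key. Shares no code
# with the package's canonicalization.
oracle_pair_key <- function(ringA, ringB) {
  s <- function(x) paste0(sort(x), collapse = "")
  mir <- function(x) 8 - x
  keys <- character(0)
  for (a in list(ringA, mir(ringA)))
    for (b in list(ringB, mir(ringB)))
      keys <- c(keys, paste(s(a), s(b), sep = "|"), paste(s(b), s(a), sep = "|"))
  min(keys)
}

all_position_subsets <- function() {
  subsets <- list(integer(0))
  for (k in 1:5)
    subsets <- c(subsets, utils::combn(2:6, k, simplify = FALSE))
  subsets
}
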