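Package: nrslab
Title: Slab-Model Analysis of Neutron Reflectivity from Adsorbed Protein Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-models and co-refines specular neutron reflectivity from
    antibody layers adsorbed at the silicon-oxide/water interface. A multi-slab
    protein layer model on Si/SiO2 is refined simultaneously against several
    isotopic solvent contrasts (D2O, contrast-matched water, H2O) by the
    optical (Abeles) matrix method with Nevot-Croce roughness and Gaussian
    resolution smearing. Fits are converted to protein volume-fraction
    profiles, adsorbed amounts (mg/m^2), per-slab mass fractions and
    mass-center-to-surface distances, with bootstrap uncertainties and
    elbow-style slab-count selection. Companion tools convert ellipsometric
    layer parameters to surface densities via De Feijter's formula, compute
    interfacial density profiles, mass centers, atomic contact counts and RMSD
    from atomic coordinates, and generate realistic synthetic multi-contrast
    datasets and pseudo-protein conformations with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    minpack.lm,
    pracma,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
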