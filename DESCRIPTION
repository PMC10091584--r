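Package: ldrbm
Title: Laplace-Dirichlet Rule-Based Generation of Myocardial Fiber Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates myocardial fiber, sheet and sheet-normal direction
    fields on labeled volumetric meshes of idealized and realistic cardiac
    geometries (ventricular and spherical slabs, left ventricles, left atria)
    using Laplace-Dirichlet Rule-Based Methods. Provides a Gmsh '.msh' reader
    for labeled tetrahedral and hexahedral meshes, linear finite-element
    solvers for the harmonic transmural and apico-basal potentials, the
    orthonormal local frame construction and Rodrigues axis rotations with
    linear transmural helical/sheetlet angle laws, programmatic labeled-mesh
    fixtures, a mesh-sensitivity angular-error analysis, ParaView-consumable
    VTU output, and a parameter-file driven command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
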