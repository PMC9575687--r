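Package: manifoldCM
Title: Conformational Motions and Free-Energy Landscapes from Cryo-EM
    Projection Manifolds
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recovery of a molecular machine's conformational continuum,
    per-state occupancy map and free-energy landscape from ensembles of
    single-particle cryo-EM projection images grouped by projection
    direction. Each projection direction's image stack is embedded with
    diffusion maps (or PCA); the two-dimensional eigenvector subspaces
    that house each conformational motion as a parabolic point cloud are
    identified while parabolic harmonics are excluded; misaligned
    eigenfunctions are counter-rotated by composed planar rotations found
    with a 2D-histogram occupancy search; each realigned subspace is
    partitioned into contiguous equal-area conformational bins using
    alpha-shape polygons and an anchored ray sweep; and per-bin image
    indices are intersected across projection directions into an
    n-dimensional occupancy map converted to free energies by Boltzmann
    statistics. A ground-truth synthetic continuum generator (hinged
    pseudo-atomic toy models, projection rendering, CTF, calibrated
    Gaussian noise, nonuniform occupancies) makes every stage testable
    without external data. Includes MRC/MRCS and STAR-style metadata I/O
    and a Fourier shell correlation utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry-utils.R'
    'alphashape.R'
    'config.R'
    'conic.R'
    'toy-model.R'
    'simulate.R'
    'embedding.R'
    'fsc.R'
    'realign.R'
    'partition.R'
    'landscape.R'
    'mrc-io.R'
    'pipeline.R'
    'star-io.R'
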