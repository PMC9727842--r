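# Synthetic region atlas, version 1.
#
# Ellipsoidal proxy regions on the 95 x 79 x 79 template-space grid
# (x: left-right, y: posterior-anterior, z: inferior-superior axial slices;
# 1-based voxel coordinates of the ellipsoid centre, semi-axes in voxels).
# These are reproducible geometric stand-ins at plausible template locations,
# not anatomical segmentations.
version: 1
reference_shape: [95, 79, 79]
regions:
  - name: posterior_cingulate
    center: [48, 26, 44]
    radii: [7, 7, 7]
  - name: occipital
    center: [48, 12, 38]
    radii: [12, 7, 9]
  - name: frontal
    center: [48, 64, 44]
    radii: [14, 10, 10]
  - name: temporal
    center: [26, 46, 30]
    radii: [9, 11, 8]
  - name: parietal
    center: [48, 30, 60]
    radii: [12, 10, 8]
  - name: striatum_left
    center: [34, 48, 40]
    radii: [6, 6, 6]
  - name: pons_thalamus
    center: [48, 42, 28]
    radii: [7, 7, 8]
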