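# One scaffold design point: a single layer of 16 gelatin unit cells.
# Exactly two of {pore_side_um, fiber_width_um, porosity} may be given;
# the third is derived from the closed-form porosity of the unit cell.
material: G5
pore_side_um: 200
fiber_width_um: 100
cells_per_side: 4
layers: 1
resolution: 4
axis: x
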