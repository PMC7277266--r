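# Editable alias table mapping fine-grained ethogram labels (as used in
# video annotation) onto the eight analysis categories. Lower-cased label
# on the left, target category on the right. Labels found in neither this
# table nor the category list fall back to Other with a warning.
grazing on seagrass: Feeding
grazing: Feeding
grabbing: Feeding
jellyfish capture: Feeding
catching of jellyfish: Feeding
biting: Feeding
flipper beating: Swimming
swimming ascent: Swimming
swimming descent: Swimming
travelling: Swimming
gliding ascent: Gliding
gliding descent: Gliding
passive ascent: Gliding
resting on the bottom: Resting
motionless: Resting
self-scratching: Scratching
rubbing: Scratching
breath: Breathing
surfacing: Breathing
floating: StayingAtSurface
staying at the surface: StayingAtSurface
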