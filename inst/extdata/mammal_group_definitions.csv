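group,definition
Rodentia,Glires: rodents plus lagomorphs (rabbits and allies)
Cetacea,whales and dolphins (toothed and baleen)
Primates,primates
Laurasiatheria,laurasiatherians excluding cetaceans (carnivorans ungulates bats insectivores)
other,remaining mammals: Afrotheria Xenarthra and marsupials
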