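taxon,level,class,eco_class
Bositra,genus,Bivalvia,reclining
Neomegalodon,genus,Bivalvia,reclining
Exogyra,genus,Bivalvia,reclining
Spiriferida,order,Brachiopoda,pedicle_attached
Orthida,order,Brachiopoda,pedicle_attached
Athyridida,order,Brachiopoda,pedicle_attached
Rhynchonellida,order,Brachiopoda,pedicle_attached
Spiriferinida,order,Brachiopoda,pedicle_attached
Terebratulida,order,Brachiopoda,pedicle_attached
Orthotetida,order,Brachiopoda,cemented
Craniida,order,Brachiopoda,cemented
Thecideida,order,Brachiopoda,cemented
Productida,order,Brachiopoda,reclining
Dictyonellida,order,Brachiopoda,reclining
Lingulida,order,Brachiopoda,infaunal
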