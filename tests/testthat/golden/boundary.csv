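term,estimate,std.error,p.value,stars,adj_r_squared,n
(Intercept),0.23528973598065259,0.01023307441026438,5.2632040949060047e-85,***,0.76705141677846589,621
same_parent,0.24842110985981114,0.0088424059758898613,1.5714139536178985e-112,***,0.76705141677846589,621
distance,-0.00045089754815872806,3.8688343543089958e-05,1.6339688306922468e-28,***,0.76705141677846589,621
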