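#! FIELDS run time event
            1 0.432867691336             1
            2 1.81059223573             1
            3 1.15371883372             1
            4 0.596288668176             1
            5 0.120050842146             1
            6 0.844669548665             1
            7 0.220921813441             1
            8 0.0274935738161             1
            9 0.710096544498             1
           10 0.287202360905             1
           11 0.740516180056             1
           12 0.611155274096             1
           13 0.0155242776343             1
           14 0.025776442675             1
           15 1.23182581186             1
           16 0.289469700146             1
           17 0.467831174578             1
           18 0.463685564617             1
           19 0.895552703205             1
           20 0.794773783849             1
           21 0.171506181046             1
           22 0.236662513747             1
           23 0.0753857321848             1
           24 0.403117233038             1
           25 0.611995712036             1
           26 0.226074902959             1
           27 0.302346012244             1
           28 1.21177298147             1
           29 0.158136500524             1
           30 0.820850260003             1
           31 0.531421366146             1
           32 0.267140460905             1
           33 0.913727085557             1
           34 0.205285202689             1
           35 0.754893019389             1
           36 0.49899490336             1
           37 0.419762375516             1
           38 1.02332965746             1
           39 1.58387377153             1
           40 0.791995746489             1
           41 0.362848330025             1
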